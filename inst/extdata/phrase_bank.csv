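role,phrase
in_ltc,the decedent was a resident of a nursing home
in_ltc,the decedent had been living at an assisted living facility
in_ltc,the decedent resided in a convalescent center
in_ltc,the decedent was living in a long-term care facility
in_ltc,the decedent was a resident at a skilled nursing facility
in_ltc,staff at the care facility found the decedent unresponsive
in_ltc,a nurse at the nursing home discovered the decedent in his room
in_ltc,the decedent had resided at the assisted living facility for two years
in_ltc,the decedent was found in her room at the nursing home
in_ltc,an aide at the long-term care facility heard a noise and responded
in_ltc,the decedent lived in the memory care unit of an assisted living facility
in_ltc,the decedent was a patient at a skilled nursing facility following a stroke
in_ltc,the decedent had been admitted to the convalescent home the previous year
in_ltc,the decedent was on hospice care at a nursing facility
in_ltc,the decedent was a resident of a continuing care retirement community
in_ltc,facility staff performed rounds and found the decedent in the care facility courtyard
in_ltc,the decedent lived in a veterans home
transitioning,the decedent was to be placed in a nursing home
transitioning,the decedent was scheduled to move into assisted living
transitioning,the decedent had recently been discharged from a rehabilitation facility
transitioning,the decedent was awaiting placement in a long-term care facility
transitioning,the family planned to move the decedent to a care facility the following week
transitioning,the decedent had recently moved out of a nursing home
transitioning,the decedent was on a waiting list for an assisted living facility
transitioning,the decedent was being transferred to a skilled nursing facility
transitioning,the decedent faced imminent nursing home placement
transitioning,the decedent had toured an assisted living facility days before death
transitioning,the decedent was to be admitted to a convalescent home
transitioning,the discharge plan included transfer to long-term care
transitioning,the decedent had recently left a residential care facility against medical advice
transitioning,the move to the retirement home was planned for the following month
transitioning,the decedent was told he could no longer live alone and would need nursing home placement
transitioning,the decedent learned that morning of the planned transfer to long-term care
otherwise,the decedent feared having to go to a nursing home
otherwise,the decedent was the caregiver for a spouse living in a long-term care facility
otherwise,the decedent worried about the cost of nursing home care
otherwise,the decedent's wife had recently been admitted to a nursing home
otherwise,the decedent dreaded the possibility of placement in a care facility
otherwise,the decedent said he would rather die than go to a nursing home
otherwise,the decedent was concerned about the financial burden of assisted living
otherwise,the decedent visited his mother at the nursing home every day
otherwise,the decedent felt overwhelmed caring for a parent in a convalescent home
otherwise,the decedent expressed fear of ending up in long-term care
otherwise,the decedent faced mounting bills from his wife's nursing facility
otherwise,the decedent stated she did not want to become a burden in a care facility
otherwise,the decedent's husband was on hospice at a nursing facility
otherwise,the decedent feared losing independence and being placed in long-term care
otherwise,the decedent was distraught after placing his mother in residential care
otherwise,the decedent's sister had declined after entering an assisted living facility
distractor,the decedent lived in a group home
distractor,the decedent had a history of long-term unemployment
distractor,the decedent had a long-term history of alcohol abuse
distractor,the decedent reported long-term use of prescription opioids
distractor,the residence was located in a quiet residential neighborhood
distractor,the decedent was in a long-term relationship that had recently ended
distractor,the decedent was on long-term disability following a work accident
distractor,the decedent had completed a residential treatment program for substance abuse
distractor,a home health aide visited the residence weekly
distractor,the decedent had long-term financial difficulties
distractor,the decedent worked in residential construction for many years
distractor,the decedent suffered long-term effects of a prior stroke
distractor,the decedent received home care visits from a visiting nurse
distractor,police responded to the residential address after a welfare check was requested
filler,the decedent was found unresponsive at the residence
filler,a family member reported a history of depression
filler,the decedent had chronic back pain
filler,toxicology was positive for prescribed medication
filler,no suicide note was found at the scene
filler,a handwritten note was located near the decedent
filler,the decedent had recently lost his spouse
filler,the medical history included coronary artery disease and diabetes
filler,neighbors had not seen the decedent for several days
filler,the weapon was recovered at the scene
filler,the decedent had expressed hopelessness in recent weeks
filler,family reported increasing confusion and memory problems
filler,emergency services responded but resuscitation was unsuccessful
filler,the decedent had difficulty sleeping and poor appetite
filler,the decedent had stopped taking his medications
filler,the decedent had recently been hospitalized for pneumonia
filler,the decedent used a walker for mobility
filler,the decedent's driver license had been revoked the prior year
filler,hearing and vision had declined over the past year
filler,the decedent complained of constant pain
filler,the decedent was pronounced dead at the scene
filler,the autopsy findings were consistent with the reported manner of death
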