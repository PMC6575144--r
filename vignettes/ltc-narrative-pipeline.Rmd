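---
title: "Identifying long-term-care-associated suicides from death-investigation narratives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying long-term-care-associated suicides from death-investigation narratives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mortality surveillance systems for violent deaths attach a free-text
coroner/medical-examiner (CME) narrative to each decedent record, alongside
structured fields (demographics, manner and means of death, circumstance
flags, and injury/death location codes). For suicides among older adults,
no structured code isolates residential long-term care (LTC): the nearest
injury-location code, "supervised residential facility" (SRF), also covers
group homes and has poor sensitivity, and the "LTC/nursing home" death
location records where a person died, not where the self-harm occurred.
Deaths *associated* with LTC without occurring inside a facility — a person
about to be placed in a nursing home, a caregiver of a spouse in assisted
living, someone frightened by the financial burden of care — carry no
location signature at all.

`ltcsuicide` implements, as a reusable and fully tested pipeline, the
narrative-classification approach to this problem:

1. **Keyword seeding.** Candidate narratives are found by substring search
   for LTC-related terms; a random sample is annotated by two raters to
   build an initial labeled set (by default 103 positives and 264
   negatives, mirroring the published workflow).
2. **Random-forest triage.** Narratives are converted to tf-idf vectors
   over unigrams and bigrams and a 1500-tree random forest assigns each
   unlabeled narrative a probability of LTC association (the fraction of
   trees voting positive).
3. **Human-in-the-loop retraining.** A batch (default 41) of narratives
   with probabilities spanning the ambiguous band 0.10–0.90 is annotated,
   adjudicated, added to the labeled set, and the forest retrained.
4. **Categorization.** Final positives (probability strictly above 0.50)
   receive one of four categories: living in LTC, transitioning into or
   out of LTC, otherwise associated, or not associated (false positive).
5. **Validation and description.** The structured location codes are
   cross-tabulated against the classifier (Cohen's $\kappa$ with the
   Fleiss–Cohen–Everitt asymptotic CI, sensitivity/specificity with exact
   binomial CIs); decedents are characterized by group with small-cell
   suppression; annual counts in early-reporting states are tested for
   trend with a hand-rolled IRLS Poisson regression.

Because real corpora of this kind are restricted-access, the package ships
a calibrated synthetic-corpus generator with known ground truth and
simulated annotators, so every stage — including the full active-learning
loop — runs and is tested end to end with no external data.

## The synthetic world

`generator_config()` defaults state the conditions of the surveillance
corpus the package emulates:

* 47 759 analytic deaths (suicides, undetermined, unintentional firearm)
  among adults 55 and older, 27 reporting states (13 reporting from
  2003–2004), years 2003–2015;
* narrative lengths with mean 513.8 and SD 344.2 characters;
* 2.2% of deaths LTC-associated, split 428 / 449 / 160 across the
  living-in / transitioning / otherwise subtypes;
* an SRF injury code with sensitivity 0.25 for in-facility cases and a
  false-positive rate of 157/47 331 elsewhere;
* death-location codes for in-facility cases distributed
  (57, 43, 88, 153, 87)/428 over inpatient / outpatient–ED /
  LTC-nursing-home / home / other, with ~1% LTC-nursing-home codes
  elsewhere;
* demographic, marital, manner, means, and circumstance-flag marginals per
  category matching the published characterization table;
* 5.1% blank narratives (2578/50 337), exercising the exclusion step.

Narratives are assembled from a fixed, versioned phrase bank
(`inst/extdata/phrase_bank.csv`): each positive narrative receives 2–4
category-specific signal clauses (facility residence, placement/transition,
caregiver/fear/financial), 14% of negative narratives receive
keyword-bearing distractor clauses ("group home", "long-term
unemployment"), and neutral filler clauses pad each narrative to its
sampled target length. The 14% distractor rate makes the default keyword
search return roughly 16% of the corpus as candidates while only ~2.2% are
truly positive, mirroring the published funnel (7806 candidates against
1037 final cases). Every concern (categories, lengths, codes, covariates,
oracle noise) draws from its own seeded stream, so changing one knob never
perturbs the others and generation is byte-reproducible.

**Length model.** Published information is only the mean and SD. A normal
distribution censored at the 40-character floor puts ~8% of its mass at the
floor and shrinks the realized SD by ~8%, which would violate the
generator's own contract of reproducing the configured moments within 5%.
Lengths are therefore drawn from a lognormal matched to the configured
mean/SD — the natural right-skewed shape for text lengths — whose mass
below 40 characters is negligible (~5·10⁻⁵); the floor is kept as a guard.

**Simulated annotators.** Each rater returns the true binary label flipped
with probability `error_rate`. The default 0.085 is calibrated so two
raters on balanced items show $\kappa = (1-2e)^2 = 0.69$, the published
inter-rater agreement. Discordant items are resolved by majority vote;
with two raters every disagreement is a tie, and a tie-breaking *rater*
would make double annotation worthless (effective label error would stay at
the single-rater 8.5%, and against a ~14%-positive candidate pool roughly a
third of positive labels would be flipped negatives, capping any
cross-validated F1 against those labels near 0.75). Consensus adjudication
of a *flagged* disagreement is a deliberative re-read, not a coin flip, so
the oracle models it as a fresh independent determination at the same error
rate: effective label error $e^2 + 2e(1-e)e \approx 2\%$. For human
annotation matrices supplied without an adjudicator, the designated
tie-breaking rater remains the fallback rule.

**What the generator does not emulate.** Grammar, named entities,
state-specific abstractor style, correlation between flags (each flag is
drawn independently within category), within-state population weights, and
any dependence of narrative content on the structured fields beyond the
category itself. A green end-to-end test therefore establishes that the
pipeline machinery is correct and calibrated *for a world with this
lexical structure*; it cannot certify classifier performance on real CME
prose, whose signal is messier.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `n_trees` | 1500 | published forest size; CV logging uses 300 for speed |
| `mtry` | ⌈√p⌉ | standard random-forest feature subsampling |
| decision threshold | > 0.50 | the boundary is *exclusive*: probability exactly 0.50 is "not associated" |
| band | [0.10, 0.90] | published ambiguity band, endpoints inclusive |
| `batch_size` | 41 | published annotation batch |
| `max_rounds` | 5 (`stable_positives`) | the published run used one augmentation round; the loop generalizes, stopping when the positive set changes < 1% |
| `min_df` | 2 | drops hapax features; terms in *every* fitting document are pruned (idf 0) |
| `error_rate` | 0.085 | calibrated to inter-rater $\kappa \approx 0.69$ |
| suppression threshold | 6 | counts 1–5 masked (NCHS-style); zero is not disclosive |
| trend years / states | 2005–2015, first-year ≤ 2004 | avoids artifacts from late-joining states |

## Numerical choices

* **tf-idf.** Lowercase, punctuation stripped, unigrams + bigrams, raw
  counts weighted by $\log(N/\mathrm{df})$, no length normalization (tree
  ensembles are scale-insensitive). Out-of-vocabulary terms drop at
  transform time; a model refuses to score a matrix whose vocabulary
  fingerprint differs from its training binding.
* **Class imbalance.** Each tree trains on a balanced bootstrap (the
  minority class matched by an equal-size resample of the majority),
  keeping the 0.50 threshold meaningful when the unlabeled corpus is ~98%
  negative. "Random subset of the data" is interpreted as both row
  bootstrap and per-split feature subsampling.
* **Probability.** The vote share — the fraction of trees whose leaf votes
  positive. Leaf ties break to negative, deterministically.
* **Cohen's $\kappa$.** $(p_o-p_e)/(1-p_e)$ with the large-sample
  Fleiss–Cohen–Everitt standard error and a Wald 95% CI; this reproduces
  the published CIs (0.26–0.35 and 0.14–0.20) exactly, so the unnamed
  method in the source analysis is evidently the same. Degenerate margins
  ($p_e=1$) return a flagged `NA` rather than an arbitrary value.
* **IRLS Poisson.** Year centered at its mean, start at the log mean
  count, weighted normal equations iterated to relative tolerance 1e-10
  (max 50), Wald p-value for the slope. The deviance path is recorded and
  tested to be non-increasing; an all-zero series is flagged, not fitted.
* **Exclusion order.** Age ≥ 55, then manner, then nonempty narrative; a
  record failing several filters is counted once, at its first failing
  step, so the exclusion log always reconciles exactly.

## Design decisions where the source was silent or inconsistent

* The published keyword list shows only three examples ("long-term",
  "convalescent", "residential"); the shipped default adds "nursing home",
  "assisted living", "care facility", "rehab" and is configurable.
  Matching is substring on lowercased text, deliberately high-recall.
* The LTC/nursing-home death-code margin is printed as 569 in the methods
  and 567 in the results; both yield $\kappa = 0.17$ at two decimals. The
  default replay uses 569 and both are carried in `reference_counts()`.
* The published SRF specificity of "98%" is not reproducible from the
  printed table (its cells give 99.7%); `sensitivity_specificity()`
  reports the computed value and the discrepancy is documented here rather
  than patched.
* The published characterization table prints an age test with 46 degrees
  of freedom, inconsistent with a three-group Kruskal–Wallis (df 2); the
  package computes the df-2 statistic and makes no claim about that
  printed value.
* Band sampling is stratified over ten equal probability strata spanning
  the band ("from across the distribution" states no scheme), filled
  round-robin so the batch spans the band even when strata are uneven.
* The trend regression models year-level counts with no exposure offset,
  matching the published presentation; population denominators for LTC
  residents do not exist.

## Limitations

The phrase banks are invented: no real narrative text is included or
imitated beyond its statistical silhouette. Classifier metrics on this
synthetic world are upper bounds for real-world performance. Agreement
statistics beyond 2×2 collapse (weighted or multi-category $\kappa$),
negative-binomial or joinpoint trend alternatives, and post-hoc pairwise
group comparisons are out of scope.
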