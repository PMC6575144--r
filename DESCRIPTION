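Package: ltcsuicide
Title: Surveillance of Suicides Associated with Residential Long-Term Care
    from Death-Investigation Narratives
Version: 0.1.0
Authors@R:
    person("NVDRS", "Narrative Methods Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying violent deaths associated with residential
    long-term care (nursing homes, assisted living, continuing-care
    communities) from free-text coroner/medical-examiner narratives.
    Implements keyword seeding of an initial labeled set, tf-idf
    featurization, a random-forest narrative classifier with an iterative
    human-in-the-loop (band-sampling) retraining procedure, four-way case
    categorization, agreement analysis of structured location codes against
    the classifier (Cohen's kappa, sensitivity/specificity), decedent
    characterization tables with small-cell suppression, and Poisson trend
    regression of annual counts.  Because real narrative corpora of this
    kind are restricted-access, the package ships a calibrated synthetic
    corpus generator with known ground truth and simulated annotators, so
    the entire pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
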