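Package: cogclock
Title: Cognitive Clocks and Age-Acceleration Analysis for Cognitive Test Batteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds machine-learning "cognitive clocks" that predict
    chronological or biological age from summary statistics (quantifiers) of
    cognitive test index series, screens quantifiers by Pearson correlation
    with Benjamini-Hochberg control, evaluates clocks by age-stratified
    cross-validation (explained variance, MAE, MedAE), derives per-participant
    age accelerations and their correlation structure across clocks, and
    phenotypes participants by Gaussian age-weighted performance patterns
    clustered with K-means. Includes a seeded synthetic-cohort generator that
    emulates the statistical structure of campimetry and sensorimotor test
    batteries, so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    ranger,
    caret,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
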