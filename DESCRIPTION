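Package: wmhrecruit
Title: Two-Stage Recruitment Design Calculator for MRI-Screened Trials
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sample-size and cost calculator for two-stage clinical-trial
    recruitment designs in which an inexpensive prescreen (retinal
    photograph or routine clinical features) enriches the population sent
    to confirmatory MRI screening for significant white-matter
    hyperintensity (WMH) burden. Implements the unweighted 0-3 retinal,
    clinical and combined clinical-retinal risk scores and their
    regularized-regression weighted variants; MRI-only and prescreen-MRI
    recruitment estimates with attrition adjustment and a balanced
    two-group extension; screening performance metrics (sensitivity,
    false-positive rate, predictive values); CHS-grade to WMH-volume
    quadratic mapping and ten-year progression comparison; and a synthetic
    cohort generator that emulates the published ARIC late-midlife joint
    structure so every stage is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
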