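Package: rascore
Title: Diagnostic Validation of an Additive Rheumatoid Arthritis Marker Score
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build and validate an additive clinical prediction score
    for rheumatoid arthritis from six dichotomous disease markers (painful
    joints, swollen joints, elevated ESR, elevated CRP, positive rheumatoid
    factor, erosive arthritis). Provides patient-level cohort input/output
    with inclusion filtering, marker dichotomization at clinical thresholds,
    descriptive cohort statistics, a from-scratch ROC analysis with
    Hanley-McNeil and DeLong confidence intervals, a Buderer-type diagnostic
    sample-size calculation, and a calibrated synthetic cohort generator
    whose class-conditional marker model has an exact Poisson-binomial
    score-distribution oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
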