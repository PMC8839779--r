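Package: thermostress
Title: Contactless Acute-Stress Detection from Facial Thermal Imaging and
    Autonomic Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for recognising acute mental stress from
    facial infrared thermography combined with peripheral autonomic
    recordings.  Provides a seeded synthetic-cohort generator, extraction of
    median-temperature signals from 14 facial regions of interest with
    block-matching tracking, sparsity-regularised tonic/phasic decomposition
    of electrodermal activity, time/frequency/nonlinear heart-rate
    variability features, respiratory frequency estimation, paired
    Wilcoxon comparisons with Benjamini-Hochberg correction, and a
    two-stage feature-selection classifier (correlation pre-filter followed
    by nu-SVM recursive feature elimination with correlation-bias
    reduction) evaluated by leave-one-subject-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    e1071,
    jsonlite,
    splines,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
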