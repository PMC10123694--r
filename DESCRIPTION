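Package: isoruffier
Title: Isoinertial Ruffier Test Analysis: Heart-Rate Indices, VO2max
    Equivalence and Prediction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for a flywheel (isoinertial) variant of the
    Ruffier squat test of cardiorespiratory fitness. Computes the Ruffier
    and Ruffier-Dickson heart-rate recovery indices, evaluates linear
    VO2max prediction models, tests equivalence between the classic and
    isoinertial protocols with two one-sided tests (TOST) and Cohen's-d
    based margins, fits and cross-validates multiple linear regression
    models by leave-one-out, classifies fitness into pooled poor/fair/good
    categories with sensitivity, specificity and Cohen's kappa, and
    generates synthetic cohorts with the demographic and heart-rate
    structure of healthy young adults so every stage is testable without
    participant-level data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    stats,
    tibble,
    utils
Suggests:
    dplyr,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
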