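Package: ssirs
Title: Derivation, Point-Score Conversion and Validation of a Surgical
    Site Infection Risk Score
Version: 0.1.0
Authors@R: person("SSIRS", "Maintainers", email = "ssirs@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for building clinical risk scores for
    30-day surgical site infection (SSI) from tabular surgical-cohort
    data. Implements a two-stage modelling strategy: a forward-selection
    logistic model with fractional-polynomial handling of continuous
    covariates, an observed/expected procedure-group statistic (the CPT3
    score) that captures between-procedure risk heterogeneity, conversion
    of the final model to an integer bedside point score (the SSI Risk
    Score, SSIRS) by the Sullivan method, and evaluation by c-statistic,
    Hosmer-Lemeshow calibration, per-score-level exact binomial
    confidence intervals and the NNIS basic risk index comparator.
    Ships a configurable synthetic NSQIP-like cohort generator with a
    known ground-truth risk model so that every stage can be verified by
    parameter and score recovery without access to restricted registry
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
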