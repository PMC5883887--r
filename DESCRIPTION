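Package: incrisk
Title: Incremental Predictive Value of Composite Risk Scores in
    Discrete-Time Survival Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying how much a one-time survey-based
    composite risk score improves prediction of rare first-occurrence
    outcomes over a monthly-updating administrative composite risk score.
    Implements discrete-time survival analysis on a person-month array
    with survey-weighted logistic hazard models, design-based (Taylor
    linearization) cluster-robust variance and Wald tests, a nested
    model-selection ladder, actuarial life-table estimation of morbid
    risk, and ventile-based concentration-of-risk and positive-predictive
    -value evaluation with actuarial projection.  Includes a calibrated
    synthetic-cohort simulator with time-varying risk scores, attrition
    and cluster sampling so the full pipeline can be exercised and tested
    without access to restricted records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
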