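Package: iganpt
Title: External Validation Toolkit for the International IgA Nephropathy
    Prediction Tool
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates the International IgA Nephropathy Prediction Tool
    (IIgAN-PT) on patient-level cohorts and runs the full external-validation
    battery used in contemporary prognosis research: the Cox linear predictor
    and absolute risk (including the piecewise 36-month race-effect hazard),
    Chambless-Diao time-dependent C-statistic, calibration slope, integrated
    calibration index (ICI), Royston-Sauerbrei D and R-squared(D), decile
    calibration, percentile risk groups with Kaplan-Meier and Cox comparisons,
    and linear mixed-model eGFR slopes.  A synthetic-cohort generator emulates
    a modern novel-therapy IgA nephropathy cohort so that every stage of the
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
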