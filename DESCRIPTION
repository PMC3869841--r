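Package: actibout
Title: Bout and Non-Bout Analysis of Accelerometry-Derived Physical Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies moderate-to-vigorous physical activity (MVPA) from
    minute-by-minute metabolic-equivalent (MET) traces recorded by multisensor
    activity monitors. Implements four guideline MET cut-point schemes
    (absolute, age-dependent and relative to oxygen-uptake reserve), bout
    detection with and without the ten-minute bout requirement (including an
    interruption-tolerant variant), wear-time accounting with a valid-day
    filter, conversion of METs to energy expenditure with resting-energy
    imputation of non-wear time and physical activity level (PAL = TEE/REE),
    binary active/inactive classification against guideline targets with
    likelihood-ratio diagnostics, and split-sample ROC calibration of a
    non-bout MVPA cut-point equivalent to the 30 min/day bout criterion.
    A synthetic-cohort generator reproduces the statistical structure of
    healthy and COPD minute-level activity data so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
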