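Package: shouldercoi
Title: Cost-of-Illness Modelling for Shoulder Pain in Primary Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A bottom-up cost-of-illness pipeline for shoulder pain in
    primary health care: classification of ICD-10 diagnosis codes into
    shoulder-pain categories, construction of treatment episodes from
    coded visit records, unit-cost valuation of healthcare resource use,
    productivity-loss valuation under the human-capital and friction-cost
    approaches, cohort descriptive statistics with normal-approximation
    confidence intervals, high-cost subgroup and cost-concentration
    analysis, and a deterministic one-way/multi-way sensitivity engine.
    Includes a synthetic electronic-patient-record generator calibrated
    to published utilization margins so the full pipeline is testable
    without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    broom,
    dplyr,
    ggplot2,
    jsonlite,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
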