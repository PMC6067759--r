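Package: lbwtrends
Title: County-Level Racial Disparity Trend Analysis for Low Birthweight Rates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing county-level trends in black-white
    disparities in low birthweight (LBW) rates. Fits race-specific
    log-linear rate trends by ordinary least squares with a race dummy,
    a linear year term and a race-by-year interaction; classifies each
    county into one of five disparity-trend patterns (convergent with
    black improvement, convergent due to white worsening, divergent,
    persistent disparity, sustained equality); computes rate ratios and
    percent-change disparity metrics including the percent of baseline
    excess disparity eliminated; and projects counterfactual averted
    black LBW births and associated hospitalization costs. Includes a
    seeded synthetic-cohort generator that emulates county natality
    panels with known ground-truth trend parameters, so the full
    pipeline is testable without access to restricted vital-statistics
    files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    ggplot2
Config/testthat/edition: 3
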