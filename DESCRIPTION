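Package: lookback
Title: Lookback-Window Sensitivity Analysis for Claims-Based Prevalence
    and Incidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies how the length of the retrospective lookback
    window used to ascertain chronic-disease cases in administrative
    health claims distorts period prevalence, cumulative incidence, and
    incident/prevalent case classification relative to a
    reference-standard window.  Provides a seeded synthetic claims
    generator for two matched populations (an index population with
    elevated healthcare engagement and matched controls), exact age-sex
    matched cohort construction, configurable multi-source case-finding
    algorithms over hospital, physician and pharmacy claims, lookback
    sweeps with misclassification proportions, annual trend analysis with
    year-varying maximum windows, and publication-style shaded grid
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
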