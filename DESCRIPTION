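Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for pharmacovigilance signal detection
    in spontaneous-report databases distributed as delimited ASCII extracts
    (FAERS quarterly tables and Canada Vigilance extracts). Reads and
    normalizes report tables, deduplicates case versions, maps event terms
    onto a preferred-term / system-organ-class hierarchy, builds 2x2
    contingency tables against the all-other-drugs background, and computes
    four disproportionality statistics per drug-event pair: the reporting
    odds ratio (ROR), the proportional reporting ratio (PRR) with a
    Yates-corrected chi-squared statistic, the Bayesian confidence
    propagation neural network information component (IC), and the
    multi-item gamma-Poisson shrinker (EBGM). Also fits Weibull models to
    time-to-onset data, classifies hazard patterns, runs stratified subgroup
    comparisons with false-discovery-rate control, performs sensitivity
    reanalyses excluding co-medications, and ships a synthetic report
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    fitdistrplus,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
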