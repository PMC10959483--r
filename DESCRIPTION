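Package: epiphenome
Title: Ontology-Aware Longitudinal Phenome Analysis of Case-Control
    Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phenome-wide case-control analysis of coded
    electronic-health-record concept streams, motivated by studies of
    genetic versus non-genetic childhood-onset epilepsy. Parses OBO
    ontologies and propagates term annotations along is_a ancestry,
    builds analysis cohorts (eligibility filtering, one-month concept
    collapsing, propensity-score matching), runs whole-phenome and
    age-binned association scans with exact conditional odds ratios and
    Bonferroni control, quantifies healthcare utilization including the
    paediatric-to-adult transition window, analyses anti-seizure
    medication prescription patterns, and summarises two-stage
    replication concordance on the point-biserial effect-size scale. A
    seeded synthetic-EHR generator with planted odds ratios supports
    calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
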