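Package: ehretl
Title: Automated Cohort, Case-Control and Cross-Sectional Extraction from
    Longitudinal Primary-Care Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A six-stage extract-transform-load pipeline that turns raw
    longitudinal primary-care tables (practices, patients, coded clinical,
    therapy and measurement events) into analysable study datasets for
    cohort, case-control and cross-sectional designs.  Study designs are
    declared as data: an eligibility window specification, named code
    entities with incident/prevalent/exclusion semantics, a boolean
    exposure-combination grammar with strict (order-sensitive) and loose
    evaluation, randomized without-replacement matched-control selection,
    outcome and exit-date determination, baseline-variable extraction, and
    optional AES-256 encryption of the output.  Every patient rejected at
    any stage is counted against a documented reason so extractions are
    verifiable; a seeded synthetic-records generator with planted exposure
    prevalence and outcome hazards supports end-to-end validation, and
    incidence/prevalence summaries with exact Poisson and binomial
    confidence intervals support surveillance use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    openssl,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
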