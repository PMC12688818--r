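Package: pharmsig
Title: Pharmacovigilance Signal Detection and Time-to-Onset Analysis for
    Spontaneous-Report Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for disproportionality-based adverse-event
    signal detection on FAERS-style spontaneous report tables. Reads the
    quarterly "$"-delimited DEMO/DRUG/REAC/THER/OUTC/RPSR dialect,
    deduplicates case versions by the FDA-recommended rule, extracts
    primary-suspect cases for a target drug, rolls preferred terms up a
    PT/HLGT/SOC hierarchy, and screens drug-event pairs with four
    algorithms (reporting odds ratio, proportional reporting ratio with
    chi-squared, the BCPNN information component, and the multi-item
    gamma-Poisson shrinker EBGM) under a joint significance criterion,
    overall and stratified by sex. Time-to-onset analysis fits a Weibull
    distribution, classifies the failure type from the shape parameter,
    and compares sexes with Kaplan-Meier curves and a log-rank test. A
    synthetic FAERS-like generator with planted signal multipliers,
    duplicate case versions, and realistic missingness makes every stage
    testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    survival,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
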