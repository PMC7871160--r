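Package: prevapc
Title: Bayesian Age-Period-Cohort Models for Stratified Smoking Prevalence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits Bayesian binomial age-period-cohort (APC) models to
    stratified prevalence count tables, such as smoking prevalence by
    5-year age group and 3-yearly survey wave in urban and non-urban
    strata. Effects on the log-odds scale carry first-order random-walk
    smoothing priors on an unequal-interval Lexis lattice (5-year ages,
    3-year periods, 1-year birth-cohort grid), with a cell-level
    heterogeneity term for extra-binomial variation and sum-to-zero
    identification. Submodels (age, age-period, age-cohort, APC) are
    compared by the deviance information criterion. Post-processing
    yields effect-level prevalence estimates with credible intervals,
    between-stratum prevalence ratios, directly age-standardized
    prevalences, and heterogeneity diagnostics. Includes a synthetic
    survey-table generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    rjags,
    coda,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
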