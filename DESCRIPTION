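Package: crfmet
Title: Sex-Stratified Association Analysis of Cardiorespiratory Fitness and
    the Plasma Metabolome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for relating cardiorespiratory fitness (peak oxygen
    uptake) to multi-platform plasma metabolomics profiles in sex-stratified
    cohorts. Implements rank-based inverse normal (Van der Waerden) scoring
    with below-limit-of-detection handling, confounder-adjusted partial
    Pearson correlations with Fisher-z confidence intervals, a partial least
    squares rank-product permutation test for multivariate association,
    cross-validated stepwise regression with stability selection, fitness
    quartile descriptives with Welch ANOVA, and a calibrated synthetic
    cohort generator with ground truth for end-to-end testing.
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
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
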