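Package: teatgen
Title: Bayesian Threshold-Linear Sire Models for Teat Condition, Milk
    Yield and Somatic Cell Score
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative-genetic analysis of teat-end
    hyperkeratosis in dairy cattle jointly with milk yield and somatic
    cell score.  Implements a tri-variate threshold-linear sire model
    fitted by Gibbs sampling with liability augmentation, pedigree-based
    numerator relationship matrices (including their direct inverse by
    Henderson's rules with computed inbreeding), preparation of stacked
    teat-score and test-day datasets, posterior genetic-parameter
    functionals (heritability, intra-herd heritability, cow and herd
    repeatability, correlations) with highest-posterior-density
    intervals and Geweke diagnostics, liability-to-probability least
    squares means, selection-index correlated-response curves, and a
    synthetic-data generator that emulates the stacked study design for
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
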