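Package: survgsa
Title: Gene-Set Analysis for Censored Survival Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Self-contained and enrichment-style gene-set tests for
    associating pathway expression with censored survival outcomes.
    Implements two Kolmogorov-Smirnov-type enrichment scores (unweighted
    and Wald-ratio-weighted), the Global Test quadratic form on martingale
    residuals, a Wald-type sum-of-squares test, and a Global Boost Test
    based on componentwise-linear boosting of the Cox partial likelihood,
    all with unified subject-permutation inference and Benjamini-Hochberg
    false-discovery-rate control across pathways. Also provides a
    simulation framework (correlated multivariate-normal expression, Cox
    survival times with calibrated exponential censoring) for estimating
    empirical size and power of the five tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
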