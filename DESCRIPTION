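Package: retsim
Title: Monte Carlo Evaluation of Factor Retention Criteria for Continuous and Dichotomized Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for studying how factor retention criteria
    recover the number of major factors when the population deviates from the
    factor model through many weak minor factors and when items are
    dichotomized. Generates population correlation matrices with perfect simple
    structure plus geometrically decaying minor-factor loadings, samples
    multivariate-normal data, estimates Pearson and pairwise maximum-likelihood
    tetrachoric correlations, and applies nine retention criteria: the Kaiser
    eigenvalue rule, the acceleration factor (with and without the Kaiser
    bound), traditional parallel analysis (mean and 95th percentile reference),
    revised parallel analysis (with and without the Kaiser bound), Velicer's
    minimum average partial, and exploratory graph analysis (EBIC-tuned
    graphical lasso with Walktrap community detection and modularity
    selection). Includes the full factorial experiment driver and summary
    tables of expected accuracy and bias per scenario.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    parallel,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
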