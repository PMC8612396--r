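Package: parsmix
Title: Constrained Parsimonious Model-Based Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood fitting of multivariate Gaussian mixtures whose
    component covariance matrices obey tunable constraints on the ratio of
    determinants, on within-component shape (departure from sphericity) and on
    between-component shape, combined with a rotation regime (identity, equal
    or varying principal axes). A single nested ECM algorithm covers the whole
    constraint continuum and recovers the 14 classical parsimonious models as
    limit cases. Includes the weighted optimal-truncation operator, a
    BIC-type criterion whose penalty interpolates the classical
    free-parameter counts, a two-phase search over the number of components
    and constraint constants, overlap-controlled mixture simulation, and
    tidy/broom-style accessors for all fitted objects.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    readr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
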