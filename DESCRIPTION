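Package: crpolr
Title: Correlated Random Parameters Ordered Logit Models for Vehicle
    Safety-Feature Crash Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to study how driver warning systems (forward collision
    warning and blind spot monitoring) relate to multivehicle fatal crash
    involvement.  Implements a three-stage heterogeneity-aware pipeline:
    spatially matched control sampling by great-circle nearest neighbours,
    linear temporal trend coding, and ordered logit models for the number of
    warning systems on a crash-involved vehicle -- both a fixed-parameter
    baseline and a correlated random parameters model estimated by simulated
    maximum likelihood over Halton draws with an unrestricted lower-triangular
    Cholesky factor.  Includes marginal effects for ordinal outcomes,
    McFadden pseudo R-squared and likelihood-ratio model comparison, and a
    fully specified synthetic crash-table generator for validation by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pracma,
    geosphere,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
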