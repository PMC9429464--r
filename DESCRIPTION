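Package: mlsem
Title: Multilevel Structural Equation Models for Clustered Ordinal
    Questionnaire Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measurement and two-level structural modelling of a latent
    trait observed through ordinal questionnaire items in individuals
    nested within households.  Provides polychoric correlation and
    threshold estimation, diagonally weighted least squares confirmatory
    factor analysis with modification indices and stepwise freeing of
    error covariances, a full-information maximum likelihood two-level
    structural model (random-intercept latent factor, ordinal probit
    measurement) fitted by nested Gauss-Hermite quadrature, latent and
    indicator-level intraclass correlations, explained-variance and
    collinearity diagnostics, and a synthetic-data generator for
    clustered GHQ-12-style household surveys with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    mvtnorm,
    statmod,
    stats,
    graphics,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    numDeriv
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
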