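Package: wildrank
Title: Wild Bootstrap Rank Tests for Incomplete Factorial Repeated Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rank-based nonparametric inference for factorial repeated
    measures designs with missing values. Null hypotheses are formulated in
    terms of the (normalized) distribution functions and tested with
    quadratic-form statistics: the Wald-type statistic (WTS), the ANOVA-type
    statistic (ATS) with a Box-type degrees-of-freedom approximation, and the
    modified ANOVA-type statistic (MATS). Critical values are obtained both
    from the asymptotic reference distributions and from a wild bootstrap
    that multiplies each subject's centered rank vector by an i.i.d.
    mean-zero, variance-one weight (Rademacher by default). Includes a full
    simulation toolkit: Gaussian-copula generation of continuous repeated
    measures with autoregressive, independence and Toeplitz dependence
    structures, ordinal data generation, MCAR and MAR missingness mechanisms,
    and type-I error / power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
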