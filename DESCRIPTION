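Package: qgsel
Title: Quantitative Genetics of Bivariate Artificial-Selection Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of pedigree-recorded artificial-selection experiments on
    a continuous trait (body length) and a correlated binary threshold trait
    (maturity), as used in selective-breeding and fisheries-induced-evolution
    research. Provides pedigree relatedness algebra (additive relationship
    matrix, inbreeding, coancestry, inbreeding-minimizing pair assignment,
    inbreeding effective population size), two-stage family selection
    differentials and Lande-Arnold selection gradients, realized heritability
    by iterated generalized least squares, a Bayesian bivariate
    Gaussian-probit animal model fitted by Gibbs sampling with additive
    genetic, aquarium and generation random effects and an inbreeding
    covariate, posterior genetic trends with pedigree drift-null envelopes,
    recursive multivariate selection-response prediction with genetic drift,
    and a synthetic experiment generator emulating a two-stage family
    selection design with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
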