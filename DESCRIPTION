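Package: icsem
Title: Causal Network Search and Structural Equation Models for
    Correlated Traits in Pedigreed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and quantification of causal networks among
    correlated quantitative traits recorded on pedigreed animals. Fits a
    Bayesian multi-trait animal model with latent-factor structured
    genetic and residual covariances by Gibbs sampling, applies the
    Inductive Causation (IC) algorithm to posterior samples of the
    residual covariance matrix using highest-posterior-density decisions
    on partial correlations, and fits recursive structural equation
    models (SEM) with pedigree-correlated genetic effects, compared to
    the multi-trait model by the deviance information criterion (DIC).
    Includes a synthetic-data generator that simulates pedigrees and
    multi-trait phenotypes from a known recursive causal structure,
    emulating a milk fatty-acid study design.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
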