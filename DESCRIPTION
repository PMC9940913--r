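Package: crbm
Title: Compositional Restricted Boltzmann Machines for Binary Neural
    Population Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Energy-based latent-variable modeling of binarized neural
    population recordings with compositional Restricted Boltzmann Machines
    (cRBM). Hidden units carry double-rectified-linear (dReLU) potentials
    whose cumulant generating function is evaluated in closed form; models
    are fitted by persistent contrastive divergence with L1 sparsity
    regularization and RMSprop, and validated against exact enumeration on
    small systems. Includes Gibbs-sampling generation, a goodness-of-fit
    suite (moment matching, normalized RMSE, reconstruction likelihood,
    logistic-regression baseline, compositional-phase diagnostics), a
    functional-connectivity estimator based on in-silico single-neuron
    perturbations with region-level aggregation, a morphology-based
    structural-connectivity estimator, and a synthetic planted-assembly
    data generator so the whole pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    data.table,
    glmnet,
    mclust
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
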