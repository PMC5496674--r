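Package: stickcp
Title: Broken-Stick Change-Point Models with Unlabelled Sub-Groups
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and Bayesian inference tools for fixed-effect
    broken-stick change-point models in which each individual belongs to an
    unobserved change or no-change class. Provides a longitudinal data
    simulator with monotone completely-at-random drop-out, a data-augmented
    Metropolis-Hastings-within-Gibbs sampler (compiled) for the trajectory
    parameters and latent class labels, posterior summary measures for
    Bayesian study design (mean absolute error, posterior variance, highest
    posterior density interval length, change-detection probability, and
    classification AUROC), and a scenario-grid runner for sample-size
    simulation studies of cognitive-decline-style cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
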