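Package: spiketypes
Title: Functional Cell-Type Discovery from Spike Trains with Clustered Poisson GLMs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers functional cell types from binned spike-train
    recordings. Each neuron's response to an injected current is modeled by a
    Poisson generalized linear model (GLM) with a downsampled stimulus filter,
    a spike-history (self-interaction) filter, and an offset. Two routes to
    cell types are provided: a sequential pipeline that fits each neuron's GLM
    independently and then clusters the fitted self-interaction filters with a
    diagonal-covariance Gaussian mixture model, and a simultaneous method that
    fits a hierarchical mixture-of-GLMs by expectation-maximization, using a
    per-(neuron, cluster) weighted-Gaussian (Laplace) approximation to the
    posterior so that single-cell estimates borrow strength across neurons.
    Includes BIC-based model selection, held-out-neuron cross-validation,
    evaluation metrics (adjusted Rand score, thresholded filter RMS, average
    negative log-likelihood, explained-variance ratio, metadata z-scores), a
    pink-noise simulation study generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
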