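Package: mtssm
Title: State-Space Modeling of Mouse-Tracking Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Dynamic analysis of computer mouse-tracking experiments with a
    non-linear state-space model. Cursor trajectories from two-choice
    categorization tasks are reduced to movement-angle series and modeled as
    a two-component von Mises mixture whose mixing (attraction) probability
    is a logistic function of a per-subject latent AR(1) movement process
    plus a linear predictor encoding the experimental design (categorical
    factor, continuous covariate, and their interaction). Estimation couples
    a recursive Gaussian-approximation (Laplace) filter with an adaptive
    marginal Metropolis-Hastings sampler; a bootstrap particle filter is
    provided as an independent likelihood oracle. Includes simulation-based
    posterior predictive checks, attraction-probability curves, windowed
    attraction statistics, and functional clustering of latent movement
    profiles.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    pracma,
    cluster,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
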