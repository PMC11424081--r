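Package: latgrad
Title: Latitudinal Gradients of Body Shape Diversification on Phylogenies
Version: 0.1.0
Authors@R: person("latgrad", "maintainers", email = "latgrad@example.org",
    role = c("aut", "cre"))
Description: A phylogenetic comparative pipeline for studying latitudinal
    gradients in multivariate trait diversification. Assigns species to
    equal-count absolute-latitude quartiles, size-corrects linear
    measurements with phylogenetic regression residuals, fits Mk models
    with hidden rate classes and draws stochastic character maps by
    uniformization to profile latitude occupancy through time, quantifies
    morphospace dispersion (disparity, convex-hull volume, functional
    evenness) with permutation and bootstrap nulls, and estimates
    state-dependent rates of multivariate Brownian motion with a joint
    MCMC over discrete histories, background branch rates, and
    state-specific rate multipliers. Includes seedable simulators for
    birth-death trees, discrete histories, state-dependent traits,
    allometric measurements, and occurrence tables so every stage is
    testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
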