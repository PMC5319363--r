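Package: radiate
Title: Diversification, Trait Evolution and Ecospace Analysis for Adaptive Radiations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Likelihood tools for testing adaptive-radiation hypotheses on dated
    phylogenies. Fits constant, time-varying and covariate-dependent birth-death
    models with AICc model averaging, detects diversification-rate shifts with a
    simulation-calibrated stepwise AICc search, tests for fixed-time mass
    extinctions, fits single- and multi-regime Ornstein-Uhlenbeck and Brownian
    trait models over discrete-niche regime paintings (ancestral-state or
    stochastic maps), runs phylogenetic generalized least squares with model
    averaging, checks model adequacy by simulation, and builds Gower-dissimilarity
    ecospaces with phylogenetic correction, non-metric multidimensional scaling
    and convex-hull areas. Includes seeded synthetic-data generators (birth-death
    trees, Mk niche characters, regime-dependent OU traits, covariate curves and
    posterior-like tree sets) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    nlme,
    phytools,
    vegan,
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
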