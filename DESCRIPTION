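Package: crypticsite
Title: Cryptic Ligand-Binding Pocket Discovery by Adaptive Sampling,
    Markov State Models and Boltzmann-Reweighted Docking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering cryptic ligand-binding
    pockets in proteins and triaging docked poses. Implements goal-oriented
    adaptive sampling (FAST-style reward-driven seeding), Markov state model
    construction with reversible maximum-likelihood transition-matrix
    estimation, time-lagged independent component analysis (tICA) with
    VAMP-2 scoring, Boltzmann reweighting of per-conformation docking
    scores by stationary probabilities, quality-threshold pose clustering,
    ligand-stability filtering on center-of-mass RMSD traces, grid-based
    tunnel-bottleneck accessibility analysis, and Hill-equation
    concentration-response fitting. A synthetic-data module provides
    Brownian dynamics on constructed multi-well potentials, sphere-model
    receptors with planted open and buried sub-pockets, surrogate docking
    scores, and noisy dose-response data, so the full workflow runs and is
    testable without molecular-dynamics or docking engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    bio3d,
    igraph,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
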