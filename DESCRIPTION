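Package: loopmsm
Title: Markov State Model Analysis of Loop-Gating Conformational Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the opening and closing kinetics of paired
    extracellular loops (such as the tetraspanin SEL/LEL pair) from molecular
    simulation trajectories. Provides a synthetic overdamped Langevin generator
    with a multi-well gap potential as a tested stand-in for all-atom dynamics,
    RMSD-kernel featurization against k-medoid reference structures, k-means
    microstate discretization, reversible Markov state model estimation with
    implied-timescale and Chapman-Kolmogorov diagnostics, GMRQ cross-validated
    model selection, cluster-restart adaptive sampling, long-trajectory
    reconstruction by sampling the fitted chain, and a rational
    switching-function contact observable between labelled bead groups.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
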