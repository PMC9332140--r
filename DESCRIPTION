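Package: dynofield
Title: Absolute RNA Kinetics, Transcriptomic Vector Fields and Cell-Fate
    Predictions for Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates absolute RNA kinetic rate constants (transcription,
    splicing, degradation) and RNA velocities from conventional and
    metabolic-labeling single-cell expression matrices; reconstructs a
    continuous velocity vector field from sampled (state, velocity) pairs by
    sparse reproducing-kernel regression with EM-based outlier rejection;
    computes analytical differential-geometry quantities (Jacobian,
    divergence, curl, acceleration, curvature) and regulatory gene rankings;
    analyzes vector-field topology (fixed points, nullclines, trajectories,
    fate probabilities, graph pseudotime); and predicts least-action
    transition paths and in-silico perturbation outcomes. Includes an exact
    stochastic simulator of bursty transcription, splicing, degradation and
    nucleoside-analog labeling, plus a two-gene toggle-switch benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    deSolve,
    lhs,
    methods,
    minpack.lm,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
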