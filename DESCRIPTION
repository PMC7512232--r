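Package: oculochaos
Title: Nonlinear Dynamics of Eye-Movement Velocity Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting deterministic (chaotic) structure in
    fixational eye-movement velocity signals. Implements delay-coordinate
    phase-space reconstruction (average mutual information for the time lag,
    false nearest neighbours for the embedding dimension), Theiler-windowed
    Grassberger-Procaccia correlation sums, correlation dimension (D2) from
    log-log scaling regions, correlation entropy (K2) per fixation window,
    the Rosenstein largest Lyapunov exponent, FFT phase-randomised surrogate
    testing against the linear-stochastic null, space-time separation plots,
    recurrence matrices, and a session-level Wilcoxon significance layer.
    Includes a synthetic "jumping point" session generator (saccades with
    latency, fixational drift and tremor, broadband measurement noise) so the
    whole pipeline runs and is testable without eye-tracker recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
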