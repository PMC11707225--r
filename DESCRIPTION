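Package: posturekit
Title: Time-to-Boundary Posturography and Waveform PCA for Single-Leg
    Balance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for analysing single-leg balance on static and
    mediolaterally oscillating support surfaces. Covers marker and
    force-plate signal conditioning (zero-phase Butterworth filtering,
    spline resampling, perturbation-anchored trial trimming), rigid-body
    segment frames and X-Y-Z Euler joint angles for the ankle-to-torso
    chain, centre-of-pressure and mediolateral time-to-boundary stability
    metrics, a waveform principal-component procedure for group
    differences in joint-angle patterns with leave-one-out surrogate
    validation, and the accompanying inferential layer (mixed 2x2 ANOVA
    with partial eta squared, Cohen's d, stepwise regression). Includes a
    synthetic-cohort generator (platform motion, joint-angle waveforms,
    forward-kinematic marker trajectories, force-plate records with exact
    centre-of-pressure consistency) so every stage is testable without
    motion-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
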