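Package: adles
Title: Adjoint Estimation of Asymmetric Vocal-Fold Oscillator Models from Voice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis-by-synthesis tools for voice biomechanics. Implements an
    asymmetric one-mass body-cover model of the vocal folds (a pair of coupled
    Van der Pol oscillators), adjoint-state least-squares estimation of its
    parameters from a reference glottal flow (ADLES), and joint estimation of
    the oscillator parameters together with a distributed vocal-tract source
    profile from a recorded voice signal, via a forward-backward scheme that
    couples the oscillator to a one-dimensional acoustic wave equation with a
    time-reversal backward pass (ADLES-VFT). Fitted models are characterized
    as dynamical systems: Poincare sections, entrainment ratios, bifurcation
    scans, Lyapunov and Hurst exponents, and rule-based mapping of parameter
    regions to voice-pathology regimes. Includes a synthetic-case generator,
    glottal inverse filtering, and plain-text serialization of all results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    signal,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
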