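Package: gatedRNN
Title: Mean-Field Theory, Spectra, and Phase Diagrams for Gated Recurrent
    Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of continuous-time recurrent neural
    networks with multiplicative gating: an update gate that acts as an
    adaptive per-unit time constant and an output gate that modulates each
    unit's recurrent output.  Provides a fixed-step RK4 integrator for the
    full 3N-dimensional gated dynamics, a self-consistent Gaussian mean-field
    solver for fixed-point statistics, random-matrix predictions for the
    support of the instantaneous Jacobian spectrum, full Lyapunov spectra by
    QR reorthonormalization with Kaplan-Yorke dimension estimates, a
    dynamical mean-field prediction for the maximal Lyapunov exponent, and
    phase-diagram machinery covering the continuous and discontinuous
    transitions to chaos, marginal stability, integrator function, and
    gate-mediated reset experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    stats,
    grDevices,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
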