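Package: corrsync
Title: Correlated Colored-Noise Synchronization of Heterogeneous Neural Oscillators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how partially correlated Ornstein-Uhlenbeck
    (colored) noise synchronizes pairs of limit-cycle neural oscillators that
    differ in phase-response curve (PRC) shape and natural frequency. The
    package provides parametric and tabulated PRC representations with
    Fourier-coefficient access, a Langevin simulator for phase-reduced
    oscillator pairs, a spectral solver for the stationary phase-difference
    density (a first-order periodic boundary value problem with
    noise-filtered transport coefficients), synchrony metrics (Kuramoto order
    parameter, peak position, spike-time cross-correlation, susceptibility),
    a Morris-Lecar biophysical layer with adjoint PRC computation and
    Hilbert-phase reconstruction, and parameter-sweep drivers for
    correlation, noise time constant, frequency difference, and PRC
    heterogeneity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    deSolve,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
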