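Package: ratefield
Title: Spatially Distributed Excitatory-Inhibitory Rate Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and dynamical analysis of spatially distributed
    excitatory-inhibitory firing-rate networks on a periodic domain (ring or
    torus) with Gaussian distance-dependent coupling and a rectified-quadratic
    transfer function. Provides a fast fixed-step integrator with exact
    spectral (wrapped-Gaussian) coupling, analysis of the reduced two-unit
    model (fixed points, Hopf bifurcation, limit cycles, bistability),
    mode-wise linear stability of the fixed point and Floquet (monodromy
    matrix) stability of bulk oscillations, maximal Lyapunov exponents by the
    renormalized-perturbation (Benettin) method with optional frozen
    Ornstein-Uhlenbeck input noise, and population statistics
    (distance-dependent correlations, Welch power spectra with power-law
    fits, and PCA dimensionality) used to characterize spatiotemporal chaos.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
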