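Package: usooc
Title: Uncertain Stochastic Optimal Open-Loop Control for Neuromechanical Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts stochastic optimal open-loop control problems with random
    environmental parameters and internal motor noise into deterministic optimal
    control problems over the state mean, covariance and state-parameter
    cross-covariance, solves them by trapezoidal direct collocation with an
    augmented-Lagrangian nonlinear programming method, and validates the
    predicted moments by Euler-Maruyama Monte-Carlo simulation. Ships bilinear
    stabilization, inverted-pendulum forearm, planar 6-muscle arm and wrist
    reaching models, along with stiffness, co-contraction and coactivation
    metrics, Chebyshev-extrema probability sweeps and logarithmic
    uncertainty-stiffness fits for studying optimal feedforward impedance
    control under task uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
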