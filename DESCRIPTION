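Package: hpwtrack
Title: Harmonic Potential Well Confinement Analysis for Single-Particle Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects transient confinement in two-dimensional single-particle
    tracking trajectories with a hidden Markov model that switches between free
    Brownian diffusion and confinement in a mobile harmonic potential well
    (Ornstein-Uhlenbeck dynamics about a slowly diffusing center). Provides an
    exact-discretization simulator, a blocked Gibbs/Metropolis MCMC sampler for
    the joint posterior over parameters and hidden states, Gelman-Rubin
    convergence management, and a confinement-event profiling suite: lifetimes,
    radial shape statistics, repeat-event detection, exponential-mixture
    lifetime fits, quantile-quantile goodness of fit, across-trajectory
    heterogeneity tests, and conservation clustering with Shannon diversity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
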