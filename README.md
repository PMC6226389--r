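# hpwtrack

Bayesian detection and profiling of transient confinement in 2D
single-particle tracking (SPT) trajectories.

High-rate SPT of membrane molecules (e.g. nanoparticle-tagged lipids
imaged at kHz rates with nanometre localization) shows alternating
phases of free Brownian diffusion and transient trapping at
nanoscale sites. Methods that only switch an effective diffusion
coefficient often cannot see this trapping: at high frame rates the
frame-to-frame displacement of a trapped particle is comparable to the
trap size, so its short-time diffusivity barely drops. `hpwtrack`
instead models confinement explicitly and is aimed at anyone who needs
per-trajectory, uncertainty-aware segmentation into free and confined
phases plus quantitative profiles of the confinement events.

## The model

A trajectory X_i (2D, micrometres, observed at times t_i) follows a
hidden Markov model with a binary state z_i per increment:

- state chain: `π(z_{i+1} | z_i) = Bernoulli(z_{i+1}; z_i (1 − p_esc) + (1 − z_i) p_trap)`
- free (z = 0): Brownian motion, per-coordinate increment variance `2 D Δt`
- confined (z = 1): Ornstein–Uhlenbeck attraction to a well center C_i,
  using the exact discrete transition
  `X_{i+1} − X_i ~ N((C_i − X_i)(1 − e^{−κΔt}), (D/κ)(1 − e^{−2κΔt}))`
  per coordinate
- the center C_i diffuses with D_C while confined (D_C ≪ D) and with a
  fixed relocation diffusivity D_est while free.

Five parameters (D, D_C, κ, p_esc, p_trap) and the hidden path (z, C)
are sampled jointly from their posterior by a blocked MCMC: exact
forward-filter backward-sampling for the states, Kalman FFBS for the
center path, conjugate inverse-gamma draws for the diffusivities, Beta
draws for the switching probabilities, and Metropolis on log κ.
Convergence is managed with the Gelman–Rubin PSRF (threshold 1.2,
geometric run extension up to 4×10⁵ sweeps). Downstream, confinement
events are extracted by thresholding the posterior state probability at
0.5 and profiled: lifetimes and exponential-mixture fits with Q–Q
goodness of fit, radial shape statistics (mean confinement radius,
radial skewness — ≈ 0.63 for Gaussian occupation, whose radial law is
Rayleigh), 30-nm repeat-site detection, across-trajectory heterogeneity
tests, and conservation clustering with Shannon diversity.

## Worked example

Simulate a 5000-frame trajectory at 5 kHz with typical membrane
parameters (D = 0.5, D_C = 0.01 µm²/s, κ = 3000 s⁻¹, p_esc = 0.001,
p_trap = 0.002), then fit it with five chains of 2000 sweeps:

```r
library(hpwtrack)
sim <- simulate_hpw(n_frames = 5000, seed = 42)
fit <- run_hpw(sim, chains = 5, n_sweeps = 2000, burn_in = 1000, seed = 7)
tidy(fit)
#> # A tibble: 5 × 5
#>   parameter   estimate  std_error    conf_low  conf_high
#>   <chr>          <dbl>      <dbl>       <dbl>      <dbl>
#> 1 D            0.511     0.00771     0.496       0.526
#> 2 DC           0.00884   0.00197     0.00577     0.0133
#> 3 kappa     3079.      147.       2801.       3390.
#> 4 p_esc        0.00274   0.00151     0.000593    0.00649
#> 5 p_trap       0.00125   0.000603    0.000357    0.00268
```

The 95% credible intervals cover the simulation truth for D, D_C and κ
(the switching probabilities are pulled slightly toward their
informative prior, as expected for a trajectory with a handful of
events). The posterior state path recovers the simulated confinement:

```r
truth <- sim$state[-nrow(sim)]
mean(threshold_states(fit$state_prob) != truth)   # frame misclassification
#> [1] 0.00840168
compute_psrf(fit$draws)$psrf                      # all five < 1.05
```

`profile_events(fit)` returns the confinement-event table (lifetimes,
boundary/repeat flags, mean centers, shape statistics), and
`autoplot(fit)`, `plot_state_probability(fit)`, `plot_traces(fit)`
show the segmented trajectory, the per-frame confinement probability,
and the chains. A thin command-line front end with `simulate`, `fit`
and `events` subcommands lives at `inst/cli/hpwtrack.R`.

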