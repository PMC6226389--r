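---
title: "Detecting transient confinement in SPT trajectories with a harmonic-well HMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transient confinement in SPT trajectories with a harmonic-well HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpwtrack)
```

## The model

High-rate single-particle tracking (SPT) of membrane molecules shows
alternating phases of free diffusion and transient trapping. `hpwtrack`
models a 2D trajectory $X_i$ observed at times $t_i$ as a two-state
hidden Markov process. A binary state $z_i$ (0 = free, 1 = confined)
follows a Markov chain with per-frame trapping and escape probabilities:

$$\pi(z_{i+1} \mid z_i) = \mathrm{Bernoulli}\!\left(z_{i+1};\,
z_i (1 - p_{esc}) + (1 - z_i)\, p_{trap}\right).$$

While free, the particle diffuses with coefficient $D$. While confined,
it feels a harmonic restoring force toward a well center $C_i$, i.e. it
is an Ornstein–Uhlenbeck (OU) process with rate $\kappa$ (the well
strength). The frame-to-frame transition uses the *exact* OU solution:

$$X_{i+1} - X_i \sim \mathcal N\!\left( z_i (C_i - X_i)
\left(1 - e^{-\kappa \Delta t_i}\right),\;
D\left[(1 - z_i)\, 2 \Delta t_i + \tfrac{z_i}{\kappa}
\left(1 - e^{-2 \kappa \Delta t_i}\right)\right] \right)$$

per coordinate (isotropic). The exact solution matters: at a 5 kHz frame
rate with $\kappa \approx 3000\,\mathrm{s^{-1}}$, $\kappa\Delta t
\approx 0.6$, so a confined particle explores a sizeable fraction of the
well within one frame and the Euler–Maruyama step would misstate both
the pull and the variance. For $\kappa\Delta t \ll 1$ the expressions
reduce to the Euler form (checked numerically in the tests).

The well center itself diffuses — slowly ($D_C \ll D$) while the
particle is confined, and with a fixed algorithm parameter $D_{est}$
while free, so that the center can relocate between confinement sites:

$$C_{i+1} - C_i \sim \mathcal N\!\left(0,\; 2 \Delta t_i
\left[D_C z_i + D_{est}(1 - z_i)\right]\right).$$

The center exists at every increment; it simply does not enter the
particle's density while free. Five parameters are inferred per
trajectory: $D$, $D_C$, $\kappa$, $p_{esc}$, $p_{trap}$. $D_{est}$ is
fixed (by default tied to the current draw of $D$); the tests verify the
estimates are insensitive to it across a decade.

### Parameters and units

All quantities are SI-consistent: positions in micrometres, time in
seconds, diffusivities in $\mu m^2/s$, $\kappa$ in $s^{-1}$. Typical
membrane values, which are also the simulator defaults: $D = 0.5$,
$D_C = 0.01\ \mu m^2/s$, $\kappa = 3000\ s^{-1}$ (well radius
$\sqrt{D/\kappa} \approx 13$ nm), $p_{esc} = 0.001$,
$p_{trap} = 0.002$ per frame at $\Delta t = 2\times 10^{-4}$ s.

## Priors

Near-flat inverse-gamma IG(0.001, 0.001) priors on $D$ and $D_C$; a
log-uniform prior on $\kappa$ over $[1, 10^6]\ s^{-1}$; and an
*informative* Beta(1, 50) prior (mean $\approx 0.02$) on both switching
probabilities. The informative switching prior suppresses single-frame
flicker between states; with thousands of frames it is much weaker than
the data, but it does bias very small switching probabilities downward —
visible in simulations as mild underestimation of $p_{trap}$. All
hyperparameters are configurable through `hpw_priors()`.

## The sampler

`run_hpw()` runs a blocked Gibbs/Metropolis sweep with exact full
conditionals:

1. **States** $z$: discrete forward-filter backward-sample (FFBS) over
   the two-state chain; the per-increment emission is the product of the
   particle-increment and center-increment densities under each state.
2. **Centers** $C$: given $z$, each coordinate is a linear-Gaussian
   state-space model — a random walk with state-dependent step variance,
   observed during confined increments through the OU pull (the
   pseudo-observation $X_i + \Delta X_i / (1 - e^{-\kappa\Delta t})$).
   Sampled exactly by Kalman FFBS with a diffuse prior on $C_1$.
3. **Diffusivities**: the increment variances are linear in $D$ and
   $D_C$, so both have inverse-gamma full conditionals.
4. **Well strength** $\kappa$: random-walk Metropolis on $\log\kappa$
   (it enters the OU density nonlinearly). The proposal SD is adapted
   toward a 25–40% acceptance rate during burn-in only, then frozen, so
   detailed balance holds for every retained draw.
5. **Switching probabilities**: Beta conjugate draws from the transition
   counts of $z$.

The C++ kernels draw from R's RNG stream, so a run is bit-reproducible
given its seed.

### Why burn-in needs an exploration phase

The exact blocked kernel has a severe lock-in problem: given a smooth
center path, labelling everything "confined" with $\kappa \to 0$ is
self-consistent (a weak well is indistinguishable from free diffusion,
and a smooth center path is cheap under small $D_C$); conversely, once a
true event is labelled free, the center drifts away from the particle
and the state update can never re-acquire it, because confinement is
only favoured when the center is near the particle. Both modes are
nearly absorbing for single-site or blocked updates, and diagnosing them
from one chain is impossible.

`run_hpw()` therefore spends the first 40% of burn-in in an
*exploration phase*: the center is drawn from a modified conditional
with a tight tracking drift toward the particle during free increments
(relaxation 50 frames, damped process noise), and the center-increment
term is dropped from the state emission. States are then segmented
purely on the particle dynamics — the OU pull toward the local mean and
the reduced increment variance — which identifies the events reliably.
A handover sweep redraws the center from its exact conditional given
that segmentation, and the exact kernel runs from there on; every
retained draw comes from the unmodified kernel. This mirrors, inside
the sampler, the role the center-relocation diffusivity $D_{est}$ plays
in the generative model. Started at the true hidden path the exact
kernel stays there indefinitely; started from the heuristic
initialization it reaches the same region only through the exploration
phase (at the reference conditions the exact kernel alone needs several
thousand sweeps to escape the locked mode).

Initialization is deterministic and data-driven: states from
thresholding the windowed local diffusivity (window 50) at its median,
centers from a running mean of the positions, parameters by method of
moments from that segmentation. Chains differ only in their RNG streams.

### Convergence

`run_until_converged()` computes the Gelman–Rubin potential scale
reduction factor, $\sqrt{(n-1)/n + B/(nW)}$, for the five scalar
parameters across chains, declares convergence when all are below 1.2,
and doubles the run length (burn-in = half, split-chain style) up to a
cap of $4\times 10^5$ sweeps otherwise. Non-converged trajectories are
returned flagged, not errored, so population analyses can exclude them.
Per-frame states are not monitored: the PSRF of a near-binary quantity
is ill-defined, and the five parameters already require consistent state
paths across chains.

## Event profiling

- **Thresholding**: a frame is confined iff its posterior confinement
  probability exceeds 0.5; an exact tie counts as free (conservative
  toward the null state, and measure-zero in practice).
  `state_uncertainty_fraction()` reports the share of probabilities in
  (0.2, 0.8) as a confidence summary.
- **Events and lifetimes**: maximal runs of confined increments. An
  event spanning increments $a..b$ has lifetime $t_{b+1} - t_a$ (number
  of increments times $\Delta t$ for uniform sampling), so lifetimes of
  all runs partition the trajectory duration exactly, and a 50-frame
  event at 5 kHz lasts exactly 0.01 s. Lifetime analysis drops events
  touching either trajectory end (censored); shape analysis keeps them
  but requires at least 0.01 s (50 frames).
- **Shape statistics**: radii $R_i = \lVert X_i - \bar C \rVert$ about
  the event's mean posterior center give the mean confinement radius,
  the radial skewness (population moments; $\approx 0.63$ for Gaussian
  occupation, whose radial law is Rayleigh), the mean–median distance,
  and the radial SD. The radial spread is exposed both as SD and as
  variance (`radial_sd`, `radial_var`); the SD is the headline number
  since it shares units with the radius.
- **Repeat events**: an event whose mean center lies within 30 nm of
  *any* earlier event's center in the same trajectory is flagged; both
  include- and exclude-repeat analyses are supported.
- **Lifetime mixtures**: maximum-likelihood exponential and
  two-exponential mixture fits (EM to relative tolerance $10^{-8}$,
  best of 20 random restarts, components sorted by mean; the nested
  one-component solution is a floor on the log-likelihood). Q–Q
  goodness of fit reports $R^2$ about a line anchored at the first and
  third quartiles; gross misfits can push it to or below zero.
- **Heterogeneity**: Kruskal–Wallis across trajectories for lifetimes
  (skewed), one-way ANOVA for shape statistics.
- **Conservation clustering**: events are clustered on one standardized
  statistic with k-means seeded by k-means++ (squared Euclidean); the
  within-trajectory Shannon diversity $H_l = -\sum_j p_j \log p_j$
  (natural log, $0\log 0 := 0$) summed over trajectories and averaged
  over 50 restarts measures how conserved that statistic is within
  trajectories (0 = perfectly conserved, $\log k$ per trajectory at
  random). The minus sign makes "lower = more conserved" hold;
  statistics are standardized first because squared-Euclidean k-means is
  scale-sensitive and the statistics carry different units.
- **Local diffusivity**: a model-free windowed MLE
  $\hat D = \sum \lVert\Delta X\rVert^2 / (4 M \Delta t)$ (default
  window 100 frames, truncated at edges) used for visual comparison with
  the inferred states and for initializing the sampler.

## The simulator

`simulate_hpw()` draws states from the switching chain, particle
positions from the exact OU/Brownian one-step laws, and the center from
its model dynamics plus — only while free — a drift
$\alpha \Delta t (X_i - C_i)$ with $\alpha^{-1} = 50$ frames, so that
confinement onsets occur near the particle. The drift is a device of
the simulation (and of the sampler's exploration phase); it is never
part of the inferred model. The trajectory starts at the origin with
the state drawn from the chain's stationary law. Static localization
error is modelled as i.i.d. isotropic Gaussian noise added after
simulation; decimation (`subsample_trajectory()`) follows noise, in the
order of a real acquisition pipeline.

What the simulator does *not* emulate: dynamic (motion-blur)
localization error, anisotropic or multiple simultaneous wells, hop
diffusion between adjacent compartments, and tag-induced artifacts.
Passing the recovery suite therefore demonstrates correctness of the
inference under the model's own generative assumptions — it does not by
itself validate the model against every behaviour of experimental
trajectories.

## Numerical choices

- Variance floors of $10^{-12}\ \mu m^2$ in the Kalman recursions guard
  against singular filters when $D_C$ is sampled very small; the
  state filter works in per-step normalized probabilities with log
  emissions, which cannot underflow.
- Diffusivity draws are clamped to $[10^{-12}, 10^{12}]$; this only
  matters for draws from the heavy-tailed near-flat prior when a sweep
  contains no confined increment.
- The initial state law is uniform Bernoulli(1/2): with thousands of
  increments its influence is negligible, and it avoids circularity with
  the inferred switching rates.
- $\kappa$ proposals outside the prior support are rejected; with no
  confined increments $\kappa$ is drawn from its prior.
- Exact ties at the 0.5 state threshold are classified free.

## Known limitations

- **Static localization noise biases $\kappa$ upward.** The emission
  model does not include measurement noise. White position noise makes
  increments antipersistent and inflates the apparent pull, so fits on
  noisy data overestimate the well strength, increasingly so with the
  noise SD (the robustness suite measures this trend at 0–10 nm). At
  the ~2.7 nm level typical of interferometric tracking the effect is a
  few percent. Noise-aware extensions (a hidden true position) are out
  of scope.
- Confinement-strength accuracy degrades as $D_C$ approaches ~10% of
  $D$: a well that diffuses almost as fast as its particle is barely
  distinguishable from free diffusion, and the posterior SD of $\kappa$
  grows accordingly (measured in the robustness suite).
- One well at a time: revisits are handled through repeat-event
  detection, not through a multi-well model.

## Problem sizes used by the test and acceptance suites

Unit oracles run on instances of 4–5 frames (exhaustive enumeration,
dense Gaussian conditionals) and simulations of $10^4$–$10^6$ draws.
The recovery suite fits three 5000-frame trajectories with five chains
of 2000 sweeps each; the robustness sweeps use 2000-frame trajectories
with two chains of 1200 sweeps per condition. The acceptance script
fits twenty 5000-frame trajectories with two chains of 2000 sweeps.
These sizes were chosen so the full recovery design (coverage of the
95% intervals, frame misclassification, event detection) is measured at
the reference conditions with useful statistical resolution.

```{r example, eval = FALSE}
sim <- simulate_hpw(n_frames = 5000, seed = 42)
fit <- run_hpw(sim, chains = 5, n_sweeps = 2000, burn_in = 1000, seed = 7)
tidy(fit)
compute_psrf(fit$draws)
profile_events(fit, id = "sim-42")
```
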