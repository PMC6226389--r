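#' State transition probability of the confinement chain
#'
#' The hidden state is a two-state Markov chain: free (0) or confined (1).
#' Trapping happens with per-frame probability `p_trap`, escape with
#' `p_esc`, so the probability of the next state being confined is
#' `z_now * (1 - p_esc) + (1 - z_now) * p_trap`.
#'
#' @param z_next,z_now Binary states (0 = free, 1 = confined); vectorized.
#' @param p_esc,p_trap Per-frame switching probabilities in (0, 1).
#' @return Transition probability, same length as the state arguments.
#' @examples
#' transition_probability(1, 0, p_esc = 0.001, p_trap = 0.002) # 0.002
#' @export
transition_probability <- function(z_next, z_now, p_esc, p_trap) {
  check_binary(z_next, "z_next")
  check_binary(z_now, "z_now")
  stopifnot(p_esc > 0, p_esc < 1, p_trap > 0, p_trap < 1)
  p1 <- z_now * (1 - p_esc) + (1 - z_now) * p_trap
  ifelse(z_next == 1, p1, 1 - p1)
}

check_binary <- function(z, name) {
  if (!is.numeric(z) || anyNA(z) || !all(z %in% c(0, 1)))
    stop("`", name, "` must contain only 0 (free) or 1 (confined)",
         call. = FALSE)
  invisible(z)
}

#' One-step moments of the particle increment
#'
#' Per-coordinate mean and variance of `X[i+1] - X[i]`. Free state: pure
#' Brownian motion, zero mean, variance `2 * D * dt`. Confined state: the
#' exact one-step solution of the Ornstein-Uhlenbeck dynamics about the
#' center, with mean shrinkage `(C - X) * (1 - exp(-kappa * dt))` and
#' variance `(D / kappa) * (1 - exp(-2 * kappa * dt))`. The exact solution
#' matters here because at realistic frame rates a confined particle can
#' explore an appreciable fraction of the well within a single frame, which
#' an Euler-Maruyama step would mis-state.
#'
#' @param offset Center-minus-particle offset `C - X` (per coordinate;
#'   ignored in the free state).
#' @param state Binary state (0/1), vectorized.
#' @param D Particle diffusivity, um^2/s.
#' @param kappa Well strength, 1/s.
#' @param dt Time increment, s.
#' @return A list with numeric vectors `mean` and `var` (per coordinate).
#' @export
particle_step_moments <- function(offset, state, D, kappa, dt) {
  stopifnot(all(dt > 0), D > 0, kappa > 0)
  check_binary(state, "state")
  a <- 1 - exp(-kappa * dt)
  v_conf <- (D / kappa) * (1 - exp(-2 * kappa * dt))
  list(
    mean = state * offset * a,
    var  = ifelse(state == 1, v_conf, 2 * D * dt)
  )
}

#' Log-density of a particle increment
#'
#' Isotropic 2D Gaussian transition density of `X[i+1] - X[i]` given the
#' current position, center, and hidden state (exact OU discretization when
#' confined, Brownian when free).
#'
#' @param dx,dy Observed displacement components, um.
#' @param x,y Current particle position, um.
#' @param cx,cy Current well-center position, um (ignored when free).
#' @inheritParams particle_step_moments
#' @return Log-density, vectorized over increments.
#' @export
particle_increment_logdensity <- function(dx, dy, x, y, cx, cy,
                                          state, D, kappa, dt) {
  mx <- particle_step_moments(cx - x, state, D, kappa, dt)
  my <- particle_step_moments(cy - y, state, D, kappa, dt)
  dnorm(dx, mx$mean, sqrt(mx$var), log = TRUE) +
    dnorm(dy, my$mean, sqrt(my$var), log = TRUE)
}

#' Log-density of a well-center increment
#'
#' The center performs zero-mean Brownian motion with diffusivity `DC`
#' while the particle is confined and `Dest` while it is free; the
#' per-coordinate variance over `dt` is `2 * dt * DC` or `2 * dt * Dest`.
#' The center exists at every increment even when free — it simply does not
#' enter the particle's density then.
#'
#' @param dcx,dcy Center displacement components, um.
#' @param state Binary state (0/1), vectorized.
#' @param DC,Dest Center diffusivities (confined / free), um^2/s.
#' @param dt Time increment, s.
#' @return Log-density, vectorized.
#' @export
center_increment_logdensity <- function(dcx, dcy, state, DC, Dest, dt) {
  stopifnot(all(dt > 0), DC > 0, Dest > 0)
  check_binary(state, "state")
  s <- sqrt(2 * dt * ifelse(state == 1, DC, Dest))
  dnorm(dcx, 0, s, log = TRUE) + dnorm(dcy, 0, s, log = TRUE)
}

#' Complete-data log-likelihood of the confinement model
#'
#' Joint log-probability of the observed positions and the hidden path
#' (states and centers) under the model: the initial-state term (uniform
#' Bernoulli(1/2), see the methods vignette), the state-chain transition
#' terms, the particle increment densities, and the center increment
#' densities. The first position and center are conditioned on, not
#' modelled. Used by both the simulator tests and the sampler.
#'
#' @param data A trajectory (see [as_trajectory()]) with N rows.
#' @param path A data frame with N-1 rows and columns `state` (0/1), `cx`,
#'   `cy` — the hidden state and well center for each increment.
#' @param params An [hpw_params()] object.
#' @return A single log-probability.
#' @export
complete_loglik <- function(data, path, params) {
  data <- as_trajectory(data)
  n <- nrow(data)
  if (!is.data.frame(path) || nrow(path) != n - 1L)
    stop("`path` must have exactly N-1 rows (one per increment); got ",
         nrow(path), " for N = ", n, call. = FALSE)
  z <- path$state
  check_binary(z, "path$state")
  dt <- diff(data$time)
  i <- seq_len(n - 1L)

  ll_x <- sum(particle_increment_logdensity(
    diff(data$x), diff(data$y),
    data$x[i], data$y[i], path$cx, path$cy,
    z, params$D, params$kappa, dt
  ))
  ll_c <- if (n > 2L) {
    j <- seq_len(n - 2L)
    sum(center_increment_logdensity(
      diff(path$cx), diff(path$cy), z[j], params$DC, params$Dest, dt[j]
    ))
  } else 0
  ll_z <- log(0.5) + if (n > 2L) {
    j <- seq_len(n - 2L)
    sum(log(transition_probability(z[j + 1L], z[j],
                                   params$p_esc, params$p_trap)))
  } else 0
  ll_x + ll_c + ll_z
}
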