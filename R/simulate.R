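#' Simulate a confinement-switching trajectory
#'
#' Generates a 2D trajectory from the harmonic-well confinement model
#' together with its ground-truth hidden path. States evolve by the
#' two-state Markov chain; the particle moves by exact one-step OU dynamics
#' when confined and Brownian motion when free; the well center diffuses
#' with `DC` when confined and, when free, with `Dest` plus a drift
#' `alpha * dt * (X - C)` pulling it toward the particle so that
#' confinement onsets start near the particle. The drift is a
#' simulation-only device and is never part of the inference model.
#'
#' The returned tibble has one row per frame: `time`, `x`, `y`, and the
#' ground truth `state`, `cx`, `cy` for the increment starting at that
#' frame (`NA` on the last row, which starts no increment).
#'
#' @param params An [hpw_params()] object. Defaults match a well-studied
#'   simulation regime: `D = 0.5`, `DC = 0.01` um^2/s, `kappa = 3000` 1/s,
#'   `p_esc = 0.001`, `p_trap = 0.002`.
#' @param n_frames Number of frames N (default 5000).
#' @param dt Uniform frame interval, s (default 2e-4, i.e. 5 kHz).
#' @param center_tracking_rate Drift rate `alpha` of the center toward the
#'   particle while free, 1/s. Default relaxation time is 50 frames,
#'   `alpha = 1 / (50 * dt)`.
#' @param init_state Initial state, or `NULL` (default) to draw it from the
#'   stationary law of the switching chain,
#'   `P(confined) = p_trap / (p_trap + p_esc)`.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `time`, `x`, `y`, `state`, `cx`, `cy`.
#' @examples
#' sim <- simulate_hpw(n_frames = 1000, seed = 1)
#' mean(sim$state, na.rm = TRUE) # fraction of confined increments
#' @export
simulate_hpw <- function(params = hpw_params(), n_frames = 5000, dt = 2e-4,
                         center_tracking_rate = 1 / (50 * dt),
                         init_state = NULL, seed = NULL) {
  stopifnot(inherits(params, "hpw_params"), n_frames >= 2, dt > 0,
            center_tracking_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_frames)
  m <- n - 1L

  x <- y <- numeric(n)
  cx <- cy <- numeric(m)
  z <- integer(m)

  z[1L] <- if (is.null(init_state)) {
    as.integer(runif(1) < params$p_trap / (params$p_trap + params$p_esc))
  } else {
    check_binary(init_state, "init_state")
    as.integer(init_state)
  }

  a <- 1 - exp(-params$kappa * dt)
  sd_conf <- sqrt((params$D / params$kappa) *
                    (1 - exp(-2 * params$kappa * dt)))
  sd_free <- sqrt(2 * params$D * dt)
  sd_c_conf <- sqrt(2 * params$DC * dt)
  sd_c_free <- sqrt(2 * params$Dest * dt)
  alpha_dt <- center_tracking_rate * dt

  for (i in seq_len(m)) {
    if (z[i] == 1L) {
      x[i + 1L] <- x[i] + (cx[i] - x[i]) * a + rnorm(1, 0, sd_conf)
      y[i + 1L] <- y[i] + (cy[i] - y[i]) * a + rnorm(1, 0, sd_conf)
    } else {
      x[i + 1L] <- x[i] + rnorm(1, 0, sd_free)
      y[i + 1L] <- y[i] + rnorm(1, 0, sd_free)
    }
    if (i < m) {
      if (z[i] == 1L) {
        cx[i + 1L] <- cx[i] + rnorm(1, 0, sd_c_conf)
        cy[i + 1L] <- cy[i] + rnorm(1, 0, sd_c_conf)
      } else {
        cx[i + 1L] <- cx[i] + alpha_dt * (x[i] - cx[i]) + rnorm(1, 0, sd_c_free)
        cy[i + 1L] <- cy[i] + alpha_dt * (y[i] - cy[i]) + rnorm(1, 0, sd_c_free)
      }
      p_conf <- z[i] * (1 - params$p_esc) + (1 - z[i]) * params$p_trap
      z[i + 1L] <- as.integer(runif(1) < p_conf)
    }
  }

  tibble::tibble(
    time = (seq_len(n) - 1) * dt,
    x = x, y = y,
    state = c(z, NA_integer_),
    cx = c(cx, NA_real_), cy = c(cy, NA_real_)
  )
}

#' Add static localization noise to a trajectory
#'
#' Adds i.i.d. zero-mean isotropic Gaussian noise of standard deviation
#' `sd` to every position, emulating the frame-independent (static)
#' localization error of the camera/detection step. `sd = 0` returns the
#' input unchanged.
#'
#' @param data A trajectory tibble.
#' @param sd Noise standard deviation per coordinate, um (e.g. 0.0027 for a
#'   2.7 nm localization error).
#' @param seed Optional integer seed.
#' @return The trajectory with perturbed `x`, `y`.
#' @export
add_localization_noise <- function(data, sd, seed = NULL) {
  data <- as_trajectory(data)
  if (!is.numeric(sd) || length(sd) != 1L || sd < 0)
    stop("`sd` must be a single non-negative number (um)", call. = FALSE)
  if (sd == 0) return(data)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  data$x <- data$x + rnorm(n, 0, sd)
  data$y <- data$y + rnorm(n, 0, sd)
  data
}

#' Subsample a trajectory
#'
#' Keeps every `factor`-th frame starting from the first, preserving time
#' stamps. Decimation is the standard mitigation for dynamic (motion-blur)
#' localization error at very high acquisition rates, e.g. 10-fold from
#' 50 kHz down to 5 kHz.
#'
#' @param data A trajectory tibble.
#' @param factor Positive integer decimation factor; 1 is the identity.
#' @return The subsampled trajectory, `ceiling(N / factor)` rows.
#' @export
subsample_trajectory <- function(data, factor) {
  data <- as_trajectory(data)
  if (!is.numeric(factor) || length(factor) != 1L ||
      factor < 1 || factor != as.integer(factor))
    stop("`factor` must be a positive integer", call. = FALSE)
  data[seq(1L, nrow(data), by = as.integer(factor)), , drop = FALSE]
}
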