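# Blocked MCMC for the confinement model. One sweep updates, in order:
# hidden states z (discrete FFBS), well centers C (Kalman FFBS per
# coordinate), diffusivities D and DC (inverse-gamma conjugate draws),
# well strength kappa (Metropolis on log scale), switching probabilities
# (Beta conjugate draws). All full conditionals are exact; kappa is the
# only Metropolis step because it enters the OU density nonlinearly.

VAR_FLOOR <- 1e-12   # um^2, guards Kalman recursions when DC is tiny
C_PRIOR_VAR <- 100   # um^2, diffuse prior on the initial center

rinvgamma1 <- function(shape, rate) 1 / rgamma(1L, shape = shape, rate = rate)

# Per-increment working quantities shared by several updates
ou_terms <- function(kappa, D, dt) {
  a <- 1 - exp(-kappa * dt)
  list(a = a, v_conf = (D / kappa) * (1 - exp(-2 * kappa * dt)),
       v_free = 2 * D * dt)
}

#' Sample the hidden state path from its full conditional
#'
#' Exact draw of the binary confinement path by forward filtering and
#' backward sampling over the two-state chain, with per-increment emission
#' equal to the particle-increment density times the center-increment
#' density for the candidate state.
#'
#' @param data A trajectory tibble.
#' @param centers A data frame with columns `cx`, `cy` (length N-1).
#' @param params An [hpw_params()] object.
#' @param center_weight Power applied to the center-increment part of the
#'   emission. 1 (default) is the exact full conditional; values below 1
#'   are used only while burning in, to keep early sweeps from locking
#'   states to an arbitrary initial center path.
#' @return Integer vector of states, length N-1.
#' @export
sample_states <- function(data, centers, params, center_weight = 1) {
  data <- as_trajectory(data)
  n <- nrow(data)
  m <- n - 1L
  dt <- diff(data$time)
  dx <- diff(data$x); dy <- diff(data$y)
  i <- seq_len(m)
  ou <- ou_terms(params$kappa, params$D, dt)

  logf1 <- dnorm(dx, (centers$cx - data$x[i]) * ou$a, sqrt(ou$v_conf), log = TRUE) +
    dnorm(dy, (centers$cy - data$y[i]) * ou$a, sqrt(ou$v_conf), log = TRUE)
  logf0 <- dnorm(dx, 0, sqrt(ou$v_free), log = TRUE) +
    dnorm(dy, 0, sqrt(ou$v_free), log = TRUE)
  if (m > 1L) {
    j <- seq_len(m - 1L)
    dcx <- diff(centers$cx); dcy <- diff(centers$cy)
    s_conf <- sqrt(2 * dt[j] * params$DC)
    s_free <- sqrt(2 * dt[j] * params$Dest)
    logf1[j] <- logf1[j] + center_weight *
      (dnorm(dcx, 0, s_conf, log = TRUE) + dnorm(dcy, 0, s_conf, log = TRUE))
    logf0[j] <- logf0[j] + center_weight *
      (dnorm(dcx, 0, s_free, log = TRUE) + dnorm(dcy, 0, s_free, log = TRUE))
  }
  ffbs_binary_cpp(logf0, logf1, params$p_esc, params$p_trap, 0.5)
}

#' Sample the well-center path from its full conditional
#'
#' Given the states, each coordinate of the center path is the latent state
#' of a linear-Gaussian model: a random walk with step variance
#' `2 * DC * dt` (confined) or `2 * Dest * dt` (free), observed during
#' confined increments through the OU mean of the particle displacement.
#' The draw is exact by Kalman forward filtering and backward sampling,
#' started from a diffuse Gaussian prior on the initial center.
#'
#' @param data A trajectory tibble.
#' @param states Integer vector of 0/1 states, length N-1.
#' @param params An [hpw_params()] object.
#' @param tracking_rate Drift rate (1/s) of the center toward the particle
#'   during free increments. 0 (default) is the exact full conditional of
#'   the model; positive values reproduce the simulator's center-tracking
#'   device and are used only while burning in, to let the center
#'   re-acquire the particle between confinement sites.
#' @return A tibble with columns `cx`, `cy`, length N-1.
#' @export
sample_centers <- function(data, states, params, tracking_rate = 0) {
  data <- as_trajectory(data)
  n <- nrow(data)
  m <- n - 1L
  check_binary(states, "states")
  stopifnot(length(states) == m)
  dt <- diff(data$time)
  i <- seq_len(m)
  ou <- ou_terms(params$kappa, params$D, dt)

  has_obs <- states == 1L
  # a confined displacement reads dX = (C - X) * a + noise, so the
  # pseudo-observation of C is X + dX / a with variance v_conf / a^2
  obs_x <- data$x[i] + diff(data$x) / ou$a
  obs_y <- data$y[i] + diff(data$y) / ou$a
  r <- ou$v_conf / ou$a^2
  obs_x[!has_obs] <- 0; obs_y[!has_obs] <- 0; r[!has_obs] <- 1
  j <- seq_len(max(m - 1L, 0L))
  free_j <- states[j] == 0L
  q <- 2 * dt[j] * ifelse(free_j, params$Dest, params$DC)
  phi <- rep(1, m - 1L)
  ux <- uy <- rep(0, m - 1L)
  if (tracking_rate > 0 && m > 1L) {
    ad <- pmin(tracking_rate * dt[j], 1)
    phi[free_j] <- 1 - ad[free_j]
    ux[free_j] <- ad[free_j] * data$x[j][free_j]
    uy[free_j] <- ad[free_j] * data$y[j][free_j]
    # a tight tracker: with full Dest noise the center scatters far enough
    # around the particle to wreck the OU pull prediction; damp the free
    # process noise so the tracked center is a smooth local mean
    q[free_j] <- 2 * dt[j][free_j] * params$D / 50
  }

  tibble::tibble(
    cx = kalman_ffbs_cpp(obs_x, r, has_obs, q, phi, ux,
                         data$x[1L], C_PRIOR_VAR, VAR_FLOOR),
    cy = kalman_ffbs_cpp(obs_y, r, has_obs, q, phi, uy,
                         data$y[1L], C_PRIOR_VAR, VAR_FLOOR)
  )
}

#' Sample the diffusivities from their inverse-gamma full conditionals
#'
#' The per-increment variance of the particle displacement is linear in
#' `D` in both states, and the confined center increments have variance
#' linear in `DC`, so with inverse-gamma priors both full conditionals are
#' inverse-gamma. With no confined center increment, `DC` is drawn from its
#' prior (reported via attribute `from_prior`).
#'
#' @param data A trajectory tibble.
#' @param states Integer 0/1 vector, length N-1.
#' @param centers Data frame with `cx`, `cy`, length N-1.
#' @param kappa Current well strength, 1/s.
#' @param priors An [hpw_priors()] object.
#' @return Named list with elements `D` and `DC`.
#' @export
sample_diffusivities <- function(data, states, centers, kappa, priors) {
  data <- as_trajectory(data)
  n <- nrow(data)
  m <- n - 1L
  dt <- diff(data$time)
  i <- seq_len(m)
  a <- 1 - exp(-kappa * dt)
  g <- ifelse(states == 1L, (1 / kappa) * (1 - exp(-2 * kappa * dt)), 2 * dt)
  ex <- diff(data$x) - states * (centers$cx - data$x[i]) * a
  ey <- diff(data$y) - states * (centers$cy - data$y[i]) * a
  D <- rinvgamma1(priors$D_shape + m,
                  priors$D_rate + sum((ex^2 + ey^2) / (2 * g)))

  from_prior <- FALSE
  if (m > 1L) {
    j <- seq_len(m - 1L)
    conf <- which(states[j] == 1L)
  } else conf <- integer(0)
  if (length(conf) > 0L) {
    dcx <- diff(centers$cx)[conf]; dcy <- diff(centers$cy)[conf]
    DC <- rinvgamma1(priors$DC_shape + length(conf),
                     priors$DC_rate + sum((dcx^2 + dcy^2) / (4 * dt[conf])))
  } else {
    DC <- rinvgamma1(priors$DC_shape, priors$DC_rate)
    from_prior <- TRUE
  }
  # near-flat priors have heavy tails; keep prior-only draws finite
  out <- list(D = min(max(D, 1e-12), 1e12), DC = min(max(DC, 1e-12), 1e12))
  attr(out, "from_prior") <- from_prior
  out
}

# log-likelihood of the confined particle increments as a function of kappa
kappa_loglik <- function(kappa, D, dx, dy, offx, offy, dt) {
  a <- 1 - exp(-kappa * dt)
  s <- sqrt((D / kappa) * (1 - exp(-2 * kappa * dt)))
  sum(dnorm(dx, offx * a, s, log = TRUE) + dnorm(dy, offy * a, s, log = TRUE))
}

#' Metropolis update of the well strength
#'
#' Random-walk Metropolis on `log(kappa)` targeting its full conditional:
#' the OU likelihood of the confined increments under a log-uniform prior
#' on `[kappa_min, kappa_max]`. Proposals outside the support are rejected.
#' With no confined increments the draw comes straight from the prior.
#'
#' @param data A trajectory tibble.
#' @param states Integer 0/1 vector, length N-1.
#' @param centers Data frame with `cx`, `cy`.
#' @param D Current particle diffusivity.
#' @param kappa Current value.
#' @param priors An [hpw_priors()] object.
#' @param step_sd Proposal standard deviation on the log scale.
#' @return List with `kappa` and logical `accepted`.
#' @export
sample_kappa <- function(data, states, centers, D, kappa, priors,
                         step_sd = 0.2) {
  data <- as_trajectory(data)
  m <- nrow(data) - 1L
  conf <- which(states == 1L)
  if (length(conf) == 0L) {
    return(list(kappa = exp(runif(1, log(priors$kappa_min),
                                  log(priors$kappa_max))),
                accepted = TRUE))
  }
  dt <- diff(data$time)[conf]
  dx <- diff(data$x)[conf]; dy <- diff(data$y)[conf]
  offx <- centers$cx[conf] - data$x[conf]
  offy <- centers$cy[conf] - data$y[conf]

  lk_cur <- kappa_loglik(kappa, D, dx, dy, offx, offy, dt)
  prop <- exp(log(kappa) + rnorm(1, 0, step_sd))
  if (prop < priors$kappa_min || prop > priors$kappa_max)
    return(list(kappa = kappa, accepted = FALSE))
  lk_prop <- kappa_loglik(prop, D, dx, dy, offx, offy, dt)
  # log-uniform prior is flat in log(kappa); symmetric proposal in log
  if (log(runif(1)) < lk_prop - lk_cur) {
    list(kappa = prop, accepted = TRUE)
  } else {
    list(kappa = kappa, accepted = FALSE)
  }
}

#' Sample the switching probabilities from their Beta full conditionals
#'
#' Transition counts of the state path update the shared Beta prior:
#' `p_trap | z ~ Beta(a + n01, b + n00)` and
#' `p_esc | z ~ Beta(a + n10, b + n11)`.
#'
#' @param states Integer 0/1 vector.
#' @param priors An [hpw_priors()] object.
#' @return Named list with `p_esc` and `p_trap`.
#' @export
sample_switching <- function(states, priors) {
  check_binary(states, "states")
  m <- length(states)
  if (m > 1L) {
    from <- states[-m]; to <- states[-1L]
    n00 <- sum(from == 0 & to == 0); n01 <- sum(from == 0 & to == 1)
    n10 <- sum(from == 1 & to == 0); n11 <- sum(from == 1 & to == 1)
  } else n00 <- n01 <- n10 <- n11 <- 0
  list(
    p_esc  = rbeta(1L, priors$switch_a + n10, priors$switch_b + n11),
    p_trap = rbeta(1L, priors$switch_a + n01, priors$switch_b + n00)
  )
}

# Deterministic data-driven initialization: threshold the windowed local
# diffusivity at its median for z, running-mean positions for C, method of
# moments for the parameters. Identical across chains by construction.
hpw_init <- function(data, priors, window = 50L) {
  n <- nrow(data)
  m <- n - 1L
  dt <- diff(data$time)
  ld <- local_diffusivity(data, window = window)$D_local
  ld_inc <- ld[seq_len(m)]
  z0 <- as.integer(ld_inc < median(ld_inc, na.rm = TRUE))

  half <- max(1L, window %/% 2L)
  cx0 <- cy0 <- numeric(m)
  for (i in seq_len(m)) {
    idx <- max(1L, i - half):min(n, i + half)
    cx0[i] <- mean(data$x[idx]); cy0[i] <- mean(data$y[idx])
  }

  dx <- diff(data$x); dy <- diff(data$y)
  free <- which(z0 == 0L); conf <- which(z0 == 1L)
  D0 <- if (length(free) > 10L) {
    sum(dx[free]^2 + dy[free]^2) / (4 * sum(dt[free]))
  } else sum(dx^2 + dy^2) / (4 * sum(dt))
  D0 <- max(D0, 1e-8)

  kappa0 <- if (length(conf) > 10L) {
    v <- (var(data$x[conf] - cx0[conf]) + var(data$y[conf] - cy0[conf])) / 2
    if (is.finite(v) && v > 0) D0 / v else 1 / mean(dt)
  } else 1 / mean(dt)
  kappa0 <- min(max(kappa0, priors$kappa_min * 1.01), priors$kappa_max * 0.99)

  conf_c <- intersect(conf, seq_len(m - 1L))
  DC0 <- if (length(conf_c) > 10L) {
    max(sum(diff(cx0)[conf_c]^2 + diff(cy0)[conf_c]^2) /
          (4 * sum(dt[conf_c])), 1e-8)
  } else max(D0 / 50, 1e-8)

  trans_up <- sum(z0[-m] == 0 & z0[-1L] == 1) + 1
  trans_dn <- sum(z0[-m] == 1 & z0[-1L] == 0) + 1
  p_trap0 <- min(max(trans_up / (sum(z0 == 0) + 2), 1e-4), 0.5)
  p_esc0 <- min(max(trans_dn / (sum(z0 == 1) + 2), 1e-4), 0.5)

  list(z = z0, centers = tibble::tibble(cx = cx0, cy = cy0),
       D = D0, DC = DC0, kappa = kappa0, p_esc = p_esc0, p_trap = p_trap0)
}

# One full chain. Returns the retained draws plus state/center accumulators.
run_chain_engine <- function(data, priors, n_sweeps, burn_in, chain_id,
                             kappa_step = 0.2, store_paths = FALSE) {
  n <- nrow(data)
  m <- n - 1L
  init <- hpw_init(data, priors)
  z <- init$z
  centers <- init$centers
  D <- init$D; DC <- init$DC; kappa <- init$kappa
  p_esc <- init$p_esc; p_trap <- init$p_trap

  keep <- n_sweeps - burn_in
  draws <- matrix(NA_real_, keep, 5L,
                  dimnames = list(NULL, c("D", "DC", "kappa", "p_esc", "p_trap")))
  z_sum <- numeric(m)
  cx_sum <- cy_sum <- numeric(m)
  z_paths <- if (store_paths) matrix(NA_integer_, keep, m) else NULL
  acc_n <- acc_k <- 0L
  adapt_acc <- 0L; adapt_n <- 0L

  # Two-phase burn-in. Exploration phase (first 40% of burn-in): the
  # center is drawn with a tight tracking drift toward the particle
  # during free increments and the center-increment emission is excluded
  # from the state update, so states are segmented purely on the particle
  # dynamics (OU pull + reduced variance) relative to a local-mean
  # center. This finds the confinement events, which the exact kernel
  # cannot reach from a poor start because states and center path lock
  # each other in. Handover sweep: the center is redrawn from its exact
  # full conditional given the segmentation. Thereafter, including all
  # retained sweeps, the exact blocked kernel runs unchanged.
  a1 <- max(1L, as.integer(burn_in * 0.4))
  track0 <- 1 / (50 * median(diff(data$time)))

  for (s in seq_len(n_sweeps)) {
    par <- hpw_params(D = D, DC = DC, kappa = kappa,
                      p_esc = p_esc, p_trap = p_trap,
                      Dest = if (is.null(priors$Dest)) D else priors$Dest)
    if (s < a1) {
      w <- 0; tr <- track0
    } else if (s == a1) {
      w <- 0; tr <- 0   # handover: exact center before the exact z update
    } else {
      w <- 1; tr <- 0
    }
    z <- sample_states(data, centers, par, center_weight = w)
    centers <- sample_centers(data, z, par, tracking_rate = tr)
    dd <- sample_diffusivities(data, z, centers, kappa, priors)
    D <- dd$D; DC <- dd$DC
    kk <- sample_kappa(data, z, centers, D, kappa, priors, step_sd = kappa_step)
    kappa <- kk$kappa
    sw <- sample_switching(z, priors)
    p_esc <- sw$p_esc; p_trap <- sw$p_trap

    if (s <= burn_in) {
      # adapt the kappa proposal toward a 25-40% acceptance rate,
      # frozen after burn-in so detailed balance holds for retained draws
      adapt_n <- adapt_n + 1L
      adapt_acc <- adapt_acc + as.integer(kk$accepted)
      if (adapt_n == 50L) {
        rate <- adapt_acc / adapt_n
        if (rate < 0.25) kappa_step <- kappa_step * exp(-0.25)
        if (rate > 0.40) kappa_step <- kappa_step * exp(0.25)
        adapt_acc <- 0L; adapt_n <- 0L
      }
    } else {
      k <- s - burn_in
      draws[k, ] <- c(D, DC, kappa, p_esc, p_trap)
      z_sum <- z_sum + z
      cx_sum <- cx_sum + centers$cx
      cy_sum <- cy_sum + centers$cy
      if (store_paths) z_paths[k, ] <- z
      acc_n <- acc_n + 1L
      acc_k <- acc_k + as.integer(kk$accepted)
    }
  }

  list(draws = tibble::as_tibble(draws) |>
         dplyr::mutate(chain = chain_id, sweep = seq_len(keep),
                       .before = 1L),
       z_sum = z_sum, cx_sum = cx_sum, cy_sum = cy_sum,
       n_keep = keep, accept_kappa = acc_k / max(acc_n, 1L),
       kappa_step = kappa_step, z_paths = z_paths)
}

#' Fit the confinement model by MCMC
#'
#' Runs one or more independent chains of the blocked sampler on a single
#' trajectory and pools the post-burn-in draws. Each sweep updates the
#' hidden states (exact FFBS), the well-center path (Kalman FFBS), the two
#' diffusivities (conjugate inverse-gamma), the well strength (Metropolis
#' on the log scale, adapted during burn-in only), and the switching
#' probabilities (conjugate Beta). The run is fully reproducible given
#' `seed`.
#'
#' @param data A trajectory tibble (see [as_trajectory()]); at least 3
#'   frames.
#' @param chains Number of independent chains (default 5).
#' @param n_sweeps Sweeps per chain (default 2000).
#' @param burn_in Discarded initial sweeps per chain (default 1000).
#' @param priors An [hpw_priors()] object.
#' @param seed Integer seed controlling all chains.
#' @param store_paths Keep every retained hidden-state path (memory heavy);
#'   the per-frame confinement probability is always available.
#' @return An object of class `hpw_fit` with elements `draws` (tibble:
#'   chain, sweep, D, DC, kappa, p_esc, p_trap), `state_prob` (per-frame
#'   posterior confinement probability, length N-1), `center_mean` (tibble
#'   cx, cy), `accept_kappa`, and the call configuration.
#' @examples
#' sim <- simulate_hpw(n_frames = 400, seed = 1)
#' fit <- run_hpw(sim, chains = 2, n_sweeps = 200, burn_in = 100, seed = 1)
#' tidy(fit)
#' @export
run_hpw <- function(data, chains = 5, n_sweeps = 2000, burn_in = 1000,
                    priors = hpw_priors(), seed = 1L, store_paths = FALSE) {
  data <- as_trajectory(data)
  if (nrow(data) < 3L)
    stop("MCMC needs at least 3 frames; got ", nrow(data), call. = FALSE)
  stopifnot(chains >= 1, n_sweeps > burn_in, burn_in >= 0)
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max, chains)

  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    res[[ch]] <- run_chain_engine(data, priors, n_sweeps, burn_in,
                                  chain_id = ch, store_paths = store_paths)
  }

  total <- sum(vapply(res, function(r) r$n_keep, numeric(1)))
  z_sum <- Reduce(`+`, lapply(res, function(r) r$z_sum))
  cx_sum <- Reduce(`+`, lapply(res, function(r) r$cx_sum))
  cy_sum <- Reduce(`+`, lapply(res, function(r) r$cy_sum))

  structure(
    list(
      draws = dplyr::bind_rows(lapply(res, function(r) r$draws)),
      state_prob = z_sum / total,
      center_mean = tibble::tibble(cx = cx_sum / total, cy = cy_sum / total),
      accept_kappa = mean(vapply(res, function(r) r$accept_kappa, numeric(1))),
      z_paths = if (store_paths) do.call(rbind, lapply(res, function(r) r$z_paths)),
      data = data, priors = priors,
      chains = chains, n_sweeps = n_sweeps, burn_in = burn_in, seed = seed
    ),
    class = "hpw_fit"
  )
}

#' @export
print.hpw_fit <- function(x, ...) {
  cat(sprintf("<hpw_fit> %d chains x %d sweeps (burn-in %d), N = %d frames\n",
              x$chains, x$n_sweeps, x$burn_in, nrow(x$data)))
  print(tidy(x))
  invisible(x)
}
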