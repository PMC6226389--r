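# Confinement-event machinery: thresholding posterior state probabilities,
# extracting maximal runs, lifetimes, radial shape statistics, repeat-site
# detection, and the windowed local diffusivity estimate.

#' Threshold posterior confinement probabilities
#'
#' Converts per-frame posterior confinement probabilities into a binary
#' state vector: confined iff the probability exceeds 0.5. An exact tie is
#' classified free (conservative toward the null state).
#'
#' @param state_probs Numeric vector of probabilities in `[0, 1]`.
#' @return Integer vector of 0/1 states.
#' @export
threshold_states <- function(state_probs) {
  if (!is.numeric(state_probs) || anyNA(state_probs) ||
      any(state_probs < 0 | state_probs > 1))
    stop("`state_probs` must be probabilities in [0, 1]", call. = FALSE)
  as.integer(state_probs > 0.5)
}

#' Fraction of uncertain state calls
#'
#' Share of posterior confinement probabilities falling strictly between
#' `lower` and `upper` — a summary of how confidently the trajectory is
#' partitioned (small values mean most frames are called near 0 or 1).
#'
#' @param state_probs Numeric probabilities.
#' @param lower,upper Uncertainty band (default 0.2 to 0.8).
#' @return A single fraction.
#' @export
state_uncertainty_fraction <- function(state_probs, lower = 0.2, upper = 0.8) {
  mean(state_probs > lower & state_probs < upper)
}

#' Extract maximal state runs as events
#'
#' Splits a binary state vector into maximal runs: runs of 1 are
#' confinement events, runs of 0 free-diffusion events. Events containing
#' the first or last increment are flagged `touches_boundary` because their
#' full duration is not witnessed. The lifetime convention is the elapsed
#' time between the first and last increment of the run,
#' `t[end + 1] - t[start]` in frame times (a run of k increments at
#' uniform step dt lasts k * dt).
#'
#' @param states Integer 0/1 vector, length N-1 (one entry per increment).
#' @param times Frame times, length N, strictly increasing.
#' @param id Optional trajectory label attached to every event.
#' @return A tibble with one row per run: `id`, `state` ("confined" or
#'   "free"), `start_frame`, `end_frame` (increment indices), `start_time`,
#'   `end_time`, `lifetime`, `touches_boundary`.
#' @examples
#' extract_events(c(0, 1, 1, 0, 0, 1), times = seq(0, 1.2, by = 0.2))
#' @export
extract_events <- function(states, times, id = "traj") {
  check_binary(states, "states")
  m <- length(states)
  if (length(times) != m + 1L)
    stop("`times` must have length(states) + 1 entries", call. = FALSE)
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(
    id = id,
    state = ifelse(r$values == 1L, "confined", "free"),
    start_frame = starts,
    end_frame = ends,
    start_time = times[starts],
    end_time = times[ends + 1L],
    lifetime = times[ends + 1L] - times[starts],
    touches_boundary = starts == 1L | ends == m
  )
}

#' Event lifetimes for waiting-time analysis
#'
#' Returns the lifetimes of events of the requested state, optionally
#' dropping events that touch the trajectory boundary (whose true lifetime
#' is censored) — the rule used for lifetime/waiting-time analysis. Shape
#' analysis instead keeps boundary events and filters on a minimum
#' duration.
#'
#' @param events Event tibble from [extract_events()].
#' @param state Which runs to keep: "confined" (default) or "free".
#' @param exclude_boundary Drop boundary-touching events (default TRUE).
#' @param min_lifetime Keep events with `lifetime >= min_lifetime` seconds
#'   (default 0, no filter).
#' @return Numeric vector of lifetimes, seconds.
#' @export
lifetime_table <- function(events, state = "confined",
                           exclude_boundary = TRUE, min_lifetime = 0) {
  ev <- events[events$state == state, , drop = FALSE]
  if (exclude_boundary) ev <- ev[!ev$touches_boundary, , drop = FALSE]
  ev <- ev[ev$lifetime >= min_lifetime, , drop = FALSE]
  ev$lifetime
}

#' Radial shape statistics of a confinement event
#'
#' Distances `R_i` of the event's particle positions from the mean
#' posterior well center summarize the occupation profile: `mean_radius`
#' is the confinement radius; `radial_skewness` (population third
#' standardized moment) distinguishes Gaussian occupation — whose radial
#' law is Rayleigh with skewness about 0.63 — from ring-like or otherwise
#' non-Gaussian profiles; `mean_median_distance` and `radial_sd` capture
#' asymmetry and spread of the radial law. Statistics are invariant under
#' rotation and translation. A degenerate event with all radii equal has
#' zero spread and its skewness is reported as 0 with `degenerate = TRUE`.
#'
#' @param x,y Particle positions inside the event, um (at least 2 points).
#' @param cx,cy Mean posterior well center of the event, um.
#' @return One-row tibble: `mean_radius`, `radial_skewness`,
#'   `mean_median_distance`, `radial_sd`, `radial_var`, `n_points`,
#'   `degenerate`.
#' @export
shape_statistics <- function(x, y, cx, cy) {
  stopifnot(length(x) == length(y), length(cx) == 1L, length(cy) == 1L)
  if (length(x) < 2L)
    stop("shape statistics need at least 2 positions", call. = FALSE)
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  mu <- mean(r)
  m2 <- mean((r - mu)^2)   # population (biased) moments throughout
  m3 <- mean((r - mu)^3)
  degenerate <- m2 <= .Machine$double.eps * max(mu^2, 1)
  tibble::tibble(
    mean_radius = mu,
    radial_skewness = if (degenerate) 0 else m3 / m2^1.5,
    mean_median_distance = abs(mu - median(r)),
    radial_sd = sqrt(m2),
    radial_var = m2,
    n_points = length(r),
    degenerate = degenerate
  )
}

#' Flag events revisiting an earlier confinement site
#'
#' Within each trajectory, an event is a repeat if its mean well center
#' lies within `radius` of the mean center of any earlier event in the
#' same trajectory. Used to separate fresh confinement sites from
#' revisits.
#'
#' @param events Tibble with columns `id`, `cx_bar`, `cy_bar`, ordered in
#'   time within each trajectory.
#' @param radius Matching radius in um (default 0.03, i.e. 30 nm).
#' @return The events tibble with a logical `is_repeat` column.
#' @export
mark_repeats <- function(events, radius = 0.03) {
  stopifnot(all(c("id", "cx_bar", "cy_bar") %in% names(events)))
  events$is_repeat <- FALSE
  for (tid in unique(events$id)) {
    idx <- which(events$id == tid)
    for (k in seq_along(idx)) {
      if (k == 1L) next
      i <- idx[k]
      prev <- idx[seq_len(k - 1L)]
      d <- sqrt((events$cx_bar[i] - events$cx_bar[prev])^2 +
                  (events$cy_bar[i] - events$cy_bar[prev])^2)
      events$is_repeat[i] <- any(d <= radius)
    }
  }
  events
}

#' Windowed local diffusivity estimate
#'
#' Maximum-likelihood diffusion coefficient for 2D Brownian motion in a
#' centered moving window: `D_hat = sum(|dX|^2) / (4 * M * dt)` over the
#' `M` displacements in the window (truncated at the trajectory edges).
#' A model-free change-of-mobility readout, also used to initialize the
#' sampler.
#'
#' @param data A trajectory tibble with uniform time steps.
#' @param window Window size in frames (default 100).
#' @return The trajectory with an added `D_local` column (per frame).
#' @export
local_diffusivity <- function(data, window = 100L) {
  data <- as_trajectory(data)
  if (window < 2L) stop("`window` must be at least 2 frames", call. = FALSE)
  n <- nrow(data)
  dt <- diff(data$time)
  if (max(dt) - min(dt) > 1e-9 * mean(dt))
    warning("non-uniform time steps; using the mean step in each window")
  sq <- diff(data$x)^2 + diff(data$y)^2  # length n-1
  csq <- cumsum(c(0, sq))
  ct <- cumsum(c(0, dt))
  half <- window %/% 2L
  lo <- pmax(1L, seq_len(n) - half)           # first displacement index
  hi <- pmin(n - 1L, seq_len(n) + half - 1L)  # last displacement index
  m <- hi - lo + 1L
  data$D_local <- (csq[hi + 1L] - csq[lo]) / (4 * (ct[hi + 1L] - ct[lo]))
  data
}

#' Build the full confinement-event table from a fit
#'
#' End-to-end event profiling for one fitted trajectory: thresholds the
#' posterior confinement probability at 0.5, extracts maximal confined
#' runs, attaches the mean posterior well center, the radial shape
#' statistics, and the repeat-site flag. Shape statistics are computed for
#' events of at least `min_lifetime` (default 0.01 s); shorter events keep
#' `NA` shape columns but are retained for lifetime analysis.
#'
#' @param fit An `hpw_fit` object from [run_hpw()].
#' @param id Trajectory label.
#' @param min_lifetime Minimum event duration for shape statistics, s.
#' @param repeat_radius Repeat-site matching radius, um.
#' @return A tibble of confinement events with lifetimes, boundary and
#'   repeat flags, mean centers `cx_bar`, `cy_bar`, and shape statistics.
#' @export
profile_events <- function(fit, id = "traj", min_lifetime = 0.01,
                           repeat_radius = 0.03) {
  stopifnot(inherits(fit, "hpw_fit"))
  states <- threshold_states(fit$state_prob)
  ev <- extract_events(states, fit$data$time, id = id)
  ev <- ev[ev$state == "confined", , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(dplyr::bind_cols(
      ev,
      tibble::tibble(cx_bar = numeric(0), cy_bar = numeric(0)),
      shape_statistics(c(0, 1), c(0, 1), 0, 0)[0, ],
      tibble::tibble(is_repeat = logical(0))
    ))
  }
  shp <- purrr::map_dfr(seq_len(nrow(ev)), function(k) {
    fr <- ev$start_frame[k]:ev$end_frame[k]
    cxb <- mean(fit$center_mean$cx[fr])
    cyb <- mean(fit$center_mean$cy[fr])
    pos_fr <- unique(c(fr, ev$end_frame[k] + 1L))  # frames spanned by the run
    base <- tibble::tibble(cx_bar = cxb, cy_bar = cyb)
    if (ev$lifetime[k] >= min_lifetime) {
      dplyr::bind_cols(base,
                       shape_statistics(fit$data$x[pos_fr], fit$data$y[pos_fr],
                                        cxb, cyb))
    } else {
      dplyr::bind_cols(base, shape_statistics(c(0, 1), c(0, 1), 0, 0)[0, ][1, ])
    }
  })
  ev <- dplyr::bind_cols(ev, shp)
  mark_repeats(ev, radius = repeat_radius)
}
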