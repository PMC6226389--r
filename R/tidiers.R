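# broom-style summaries and ggplot2 visualisations for fitted objects.

#' Tidy posterior parameter summaries
#'
#' One row per model parameter with posterior mean, standard deviation,
#' and the central 95% credible interval from the pooled chains.
#'
#' @param x An `hpw_fit` object.
#' @param conf_level Credible-interval mass (default 0.95).
#' @param ... Unused.
#' @return A tibble: `parameter`, `estimate`, `std_error`, `conf_low`,
#'   `conf_high`.
#' @export
tidy.hpw_fit <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  purrr::map_dfr(c("D", "DC", "kappa", "p_esc", "p_trap"), function(p) {
    v <- x$draws[[p]]
    tibble::tibble(parameter = p, estimate = mean(v), std_error = sd(v),
                   conf_low = unname(quantile(v, a)),
                   conf_high = unname(quantile(v, 1 - a)))
  })
}

#' One-row fit summary
#'
#' @param x An `hpw_fit` object.
#' @param ... Unused.
#' @return A tibble with run shape, kappa acceptance rate, the largest
#'   parameter PSRF, convergence status (NA when no convergence protocol
#'   was run), and the fraction of frames with uncertain state calls.
#' @export
glance.hpw_fit <- function(x, ...) {
  psrf_max <- if (x$chains >= 2L) max(compute_psrf(x$draws)$psrf) else NA_real_
  tibble::tibble(
    n_frames = nrow(x$data),
    chains = x$chains,
    n_sweeps = x$n_sweeps,
    burn_in = x$burn_in,
    accept_kappa = x$accept_kappa,
    psrf_max = psrf_max,
    converged = if (!is.null(x$convergence)) x$convergence$converged else NA,
    uncertain_state_fraction = state_uncertainty_fraction(x$state_prob)
  )
}

#' Plot a fitted trajectory colored by confinement probability
#'
#' @param object An `hpw_fit` object.
#' @param ... Unused.
#' @return A ggplot: the trajectory path colored by the per-frame
#'   posterior confinement probability.
#' @export
autoplot.hpw_fit <- function(object, ...) {
  d <- object$data
  d$confinement <- c(object$state_prob, NA_real_)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, color = .data$confinement)) +
    ggplot2::geom_path(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::scale_color_viridis_c(limits = c(0, 1),
                                   name = expression(pi(z ~ "|" ~ X))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = "Trajectory by posterior confinement probability") +
    ggplot2::theme_minimal()
}

#' Trace plot of the posterior draws
#'
#' @param fit An `hpw_fit` object.
#' @param parameters Parameters to show.
#' @return A ggplot with one facet per parameter, colored by chain.
#' @export
plot_traces <- function(fit,
                        parameters = c("D", "DC", "kappa", "p_esc", "p_trap")) {
  stopifnot(inherits(fit, "hpw_fit"))
  long <- tidyr::pivot_longer(fit$draws, dplyr::all_of(parameters),
                              names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(.data$sweep, .data$value,
                                     color = factor(.data$chain))) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(color = "chain", y = NULL) +
    ggplot2::theme_minimal()
}

#' Per-frame confinement probability plot
#'
#' @param fit An `hpw_fit` object.
#' @param truth Optional true 0/1 state vector (length N-1) shown as a
#'   shaded band, e.g. from [simulate_hpw()] ground truth.
#' @return A ggplot of the posterior confinement probability over time.
#' @export
plot_state_probability <- function(fit, truth = NULL) {
  stopifnot(inherits(fit, "hpw_fit"))
  m <- length(fit$state_prob)
  d <- tibble::tibble(time = fit$data$time[seq_len(m)],
                      prob = fit$state_prob)
  g <- ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$prob))
  if (!is.null(truth)) {
    d$truth <- as.numeric(truth[seq_len(m)])
    g <- g + ggplot2::geom_area(data = d,
                                ggplot2::aes(y = .data$truth),
                                fill = "gold", alpha = 0.4)
  }
  g + ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = expression(pi(z[i] ~ "|" ~ X))) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Q-Q plot of lifetimes against a reference
#'
#' @param qq Result of [qq_r_squared()].
#' @return A ggplot of observed against reference quantiles with the
#'   quartile-anchored reference line.
#' @export
plot_qq <- function(qq) {
  ggplot2::ggplot(qq$points,
                  ggplot2::aes(.data$theoretical, .data$observed)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_abline(slope = qq$slope, intercept = qq$intercept,
                         color = "red") +
    ggplot2::labs(
      title = sprintf("Q-Q, R² = %.3f", qq$r_squared),
      x = "reference quantiles (s)", y = "observed quantiles (s)"
    ) +
    ggplot2::theme_minimal()
}

#' Conservation-clustering diversity curves
#'
#' @param curves Tibble from [conservation_clustering()].
#' @return A ggplot of summed Shannon diversity against the number of
#'   clusters, one line per statistic (lower = more conserved within
#'   trajectories).
#' @export
plot_conservation <- function(curves) {
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$n_clusters, .data$summed_diversity,
                               color = .data$statistic)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "number of clusters",
                  y = "summed Shannon diversity") +
    ggplot2::theme_minimal()
}
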