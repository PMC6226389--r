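# Multi-chain convergence assessment: Gelman-Rubin potential scale
# reduction factor on the five scalar parameters, and a geometric
# run-extension protocol capped at a maximum sweep count.

#' Potential scale reduction factor for one scalar
#'
#' Gelman-Rubin diagnostic from a matrix of draws (iterations in rows, one
#' column per chain): with within-chain variance `W` (mean of the chain
#' variances) and between-chain variance `B` (`n` times the variance of the
#' chain means), the statistic is `sqrt((n - 1) / n + B / (n * W))`. Values
#' near 1 indicate that the chains are sampling the same distribution.
#'
#' @param x Numeric matrix, `n` iterations by `m >= 2` chains.
#' @return A single PSRF value; `NaN` (with a warning) when the
#'   within-chain variance is zero.
#' @export
psrf <- function(x) {
  x <- as.matrix(x)
  m <- ncol(x)
  n <- nrow(x)
  if (m < 2L) stop("PSRF needs at least 2 chains", call. = FALSE)
  if (n < 2L) stop("PSRF needs at least 2 draws per chain", call. = FALSE)
  W <- mean(apply(x, 2L, var))
  B <- n * var(colMeans(x))
  if (W == 0) {
    warning("zero within-chain variance; PSRF undefined")
    return(NaN)
  }
  sqrt((n - 1) / n + B / (n * W))
}

#' PSRF for every monitored model parameter
#'
#' Computes the [psrf()] diagnostic per parameter from a pooled draws table
#' with a `chain` column, as produced by [run_hpw()]. Chains must hold
#' equally many retained draws.
#'
#' @param draws A data frame with columns `chain` and the monitored
#'   parameters.
#' @param parameters Character vector of columns to monitor.
#' @return A tibble with columns `parameter` and `psrf`.
#' @examples
#' sim <- simulate_hpw(n_frames = 300, seed = 1)
#' fit <- run_hpw(sim, chains = 2, n_sweeps = 150, burn_in = 50, seed = 1)
#' compute_psrf(fit$draws)
#' @export
compute_psrf <- function(draws,
                         parameters = c("D", "DC", "kappa", "p_esc", "p_trap")) {
  if (inherits(draws, "hpw_fit")) draws <- draws$draws
  stopifnot(is.data.frame(draws), "chain" %in% names(draws))
  parameters <- intersect(parameters, names(draws))
  split_chains <- split(draws, draws$chain)
  lens <- vapply(split_chains, nrow, integer(1))
  if (length(unique(lens)) != 1L)
    stop("chains must have equal post-burn-in lengths", call. = FALSE)
  tibble::tibble(
    parameter = parameters,
    psrf = vapply(parameters, function(p) {
      psrf(vapply(split_chains, function(ch) ch[[p]], numeric(lens[1L])))
    }, numeric(1))
  )
}

#' Fit with convergence management
#'
#' Runs multi-chain MCMC and assesses convergence by the PSRF of the five
#' model parameters. If any PSRF is at or above `threshold`, the run length
#' is doubled (burn-in kept at half the run, the usual split-chain
#' practice) and the fit repeated, up to `max_sweeps` sweeps per chain.
#' Trajectories that never converge are returned flagged, not errored, so
#' that population analyses can exclude them.
#'
#' @inheritParams run_hpw
#' @param threshold PSRF convergence threshold (default 1.2).
#' @param max_sweeps Cap on sweeps per chain (default 4e5).
#' @return An `hpw_fit` (the last run) whose `convergence` element is a
#'   `hpw_convergence` report: per-parameter PSRF, `converged` flag,
#'   `total_sweeps`, `threshold`.
#' @export
run_until_converged <- function(data, chains = 5, n_sweeps = 2000,
                                burn_in = 1000, priors = hpw_priors(),
                                seed = 1L, threshold = 1.2,
                                max_sweeps = 4e5, store_paths = FALSE) {
  stopifnot(threshold > 1, max_sweeps >= n_sweeps)
  sweeps <- n_sweeps
  burn <- burn_in
  repeat {
    fit <- run_hpw(data, chains = chains, n_sweeps = sweeps, burn_in = burn,
                   priors = priors, seed = seed, store_paths = store_paths)
    ptab <- compute_psrf(fit$draws)
    converged <- all(is.finite(ptab$psrf)) && all(ptab$psrf < threshold)
    if (converged || sweeps >= max_sweeps) break
    sweeps <- min(2L * sweeps, max_sweeps)
    burn <- sweeps %/% 2L
  }
  fit$convergence <- structure(
    list(psrf = ptab, converged = converged,
         total_sweeps = sweeps, threshold = threshold),
    class = "hpw_convergence"
  )
  fit
}

#' @export
print.hpw_convergence <- function(x, ...) {
  status <- if (x$converged) "converged" else "NOT converged"
  cat(sprintf("<hpw_convergence> %s at %d sweeps/chain (threshold %.3g)\n",
              status, x$total_sweeps, x$threshold))
  print(x$psrf)
  invisible(x)
}
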