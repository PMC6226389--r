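#' Harmonic-well model parameters
#'
#' Bundles the five inferred parameters of the confinement hidden Markov
#' model plus the fixed algorithm parameter `Dest`. Units are SI-consistent
#' throughout the package: positions in micrometres, time in seconds, so
#' diffusivities are um^2/s and the well strength `kappa` is 1/s.
#'
#' @param D Free diffusion coefficient of the particle, um^2/s.
#' @param DC Diffusion coefficient of the well center while the particle is
#'   confined, um^2/s. Expected to be much smaller than `D`.
#' @param kappa Strength of the harmonic well (mean-reversion rate of the
#'   Ornstein-Uhlenbeck dynamics), 1/s.
#' @param p_esc Per-frame probability of escaping confinement.
#' @param p_trap Per-frame probability of becoming trapped while free.
#' @param Dest Diffusion coefficient of the well center while the particle is
#'   free, um^2/s. A fixed algorithm parameter, not inferred: it only has to
#'   be large enough for the center to relocate between confinement sites.
#'
#' @return An object of class `hpw_params` (a named list).
#' @examples
#' hpw_params(D = 0.5, DC = 0.01, kappa = 3000, p_esc = 0.001, p_trap = 0.002)
#' @export
hpw_params <- function(D = 0.5, DC = 0.01, kappa = 3000,
                       p_esc = 0.001, p_trap = 0.002, Dest = D) {
  stopifnot(
    is.numeric(D), length(D) == 1L, is.finite(D), D > 0,
    is.numeric(DC), length(DC) == 1L, is.finite(DC), DC > 0,
    is.numeric(Dest), length(Dest) == 1L, is.finite(Dest), Dest > 0,
    is.numeric(kappa), length(kappa) == 1L, is.finite(kappa), kappa > 0
  )
  if (!is.numeric(p_esc) || length(p_esc) != 1L || p_esc <= 0 || p_esc >= 1)
    stop("`p_esc` must be a probability strictly inside (0, 1)", call. = FALSE)
  if (!is.numeric(p_trap) || length(p_trap) != 1L || p_trap <= 0 || p_trap >= 1)
    stop("`p_trap` must be a probability strictly inside (0, 1)", call. = FALSE)
  structure(
    list(D = D, DC = DC, kappa = kappa,
         p_esc = p_esc, p_trap = p_trap, Dest = Dest),
    class = "hpw_params"
  )
}

#' @export
print.hpw_params <- function(x, ...) {
  cat("<hpw_params>\n")
  cat(sprintf("  D      = %g um^2/s (free diffusion)\n", x$D))
  cat(sprintf("  DC     = %g um^2/s (well-center diffusion, confined)\n", x$DC))
  cat(sprintf("  kappa  = %g 1/s   (well strength)\n", x$kappa))
  cat(sprintf("  p_esc  = %g, p_trap = %g (per-frame switching)\n",
              x$p_esc, x$p_trap))
  cat(sprintf("  Dest   = %g um^2/s (center diffusion when free; fixed)\n",
              x$Dest))
  invisible(x)
}

#' Prior specification for the MCMC sampler
#'
#' Near-flat inverse-gamma priors on the diffusivities, a log-uniform prior
#' on the well strength, and informative Beta priors on the per-frame
#' switching probabilities. The informative switching prior (default
#' Beta(1, 50), mean about 0.02) restricts rapid flickering between states
#' while remaining much weaker than the data for trajectories with thousands
#' of frames.
#'
#' @param D_shape,D_rate Inverse-gamma hyperparameters for the free
#'   diffusivity `D`.
#' @param DC_shape,DC_rate Inverse-gamma hyperparameters for the confined
#'   center diffusivity `DC`.
#' @param kappa_min,kappa_max Support of the log-uniform prior on `kappa`,
#'   1/s.
#' @param switch_a,switch_b Beta hyperparameters shared by `p_esc` and
#'   `p_trap`.
#' @param Dest Fixed center diffusivity while free (um^2/s), or `NULL` to
#'   tie it to the current sample of `D` at every sweep.
#'
#' @return An object of class `hpw_priors`.
#' @export
hpw_priors <- function(D_shape = 0.001, D_rate = 0.001,
                       DC_shape = 0.001, DC_rate = 0.001,
                       kappa_min = 1, kappa_max = 1e6,
                       switch_a = 1, switch_b = 50,
                       Dest = NULL) {
  stopifnot(
    D_shape > 0, D_rate > 0, DC_shape > 0, DC_rate > 0,
    kappa_min > 0, kappa_max > kappa_min,
    switch_a > 0, switch_b > 0,
    is.null(Dest) || (is.numeric(Dest) && Dest > 0)
  )
  structure(
    list(D_shape = D_shape, D_rate = D_rate,
         DC_shape = DC_shape, DC_rate = DC_rate,
         kappa_min = kappa_min, kappa_max = kappa_max,
         switch_a = switch_a, switch_b = switch_b,
         Dest = Dest),
    class = "hpw_priors"
  )
}

#' Validate a trajectory table
#'
#' A trajectory is a data frame with numeric columns `time` (seconds,
#' strictly increasing), `x` and `y` (micrometres), at least two rows, all
#' finite. Returns the input as a tibble; extra columns are preserved.
#'
#' @param data A data frame with columns `time`, `x`, `y`.
#' @return A validated tibble.
#' @export
as_trajectory <- function(data) {
  if (!is.data.frame(data))
    stop("a trajectory must be a data frame", call. = FALSE)
  missing_cols <- setdiff(c("time", "x", "y"), names(data))
  if (length(missing_cols) > 0L)
    stop("trajectory is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  data <- tibble::as_tibble(data)
  if (nrow(data) < 2L)
    stop("a trajectory needs at least 2 frames", call. = FALSE)
  for (cl in c("time", "x", "y")) {
    if (!is.numeric(data[[cl]]) || anyNA(data[[cl]]) || any(!is.finite(data[[cl]])))
      stop("trajectory column `", cl, "` must be finite numeric", call. = FALSE)
  }
  dts <- diff(data$time)
  if (any(dts <= 0)) {
    bad <- which(dts <= 0)[1L] + 1L
    stop("trajectory times must be strictly increasing (violated at row ",
         bad, ")", call. = FALSE)
  }
  data
}
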