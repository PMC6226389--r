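# Plain-text trajectory files and run configuration. SPT has no entrenched
# binary standard, so trajectories travel as tab-separated text with
# units in the header: time_s, x_um, y_um; '#' lines are comments.

#' Read a trajectory file
#'
#' Expects tab- or whitespace-separated text with a header row naming
#' columns `time_s`, `x_um`, `y_um` (any order; extra columns ignored) and
#' optional comment lines starting with `#`. Units are taken as labelled:
#' seconds and micrometres.
#'
#' @param path File path.
#' @return A validated trajectory tibble with columns `time`, `x`, `y`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  if (length(lineno) < 2L)
    stop("file has no data rows: ", path, call. = FALSE)
  header <- strsplit(trimws(lines[lineno[1L]]), "[\t ,]+")[[1L]]
  required <- c("time_s", "x_um", "y_um")
  if (!all(required %in% header))
    stop("header must name columns time_s, x_um, y_um; got: ",
         paste(header, collapse = ", "), call. = FALSE)
  rows <- strsplit(trimws(lines[lineno[-1L]]), "[\t ,]+")
  ncols <- length(header)
  vals <- matrix(NA_real_, length(rows), ncols)
  for (r in seq_along(rows)) {
    if (length(rows[[r]]) != ncols)
      stop("line ", lineno[-1L][r], ": expected ", ncols, " fields, got ",
           length(rows[[r]]), call. = FALSE)
    v <- suppressWarnings(as.numeric(rows[[r]]))
    if (anyNA(v))
      stop("line ", lineno[-1L][r], ": non-numeric value in '",
           lines[lineno[-1L][r]], "'", call. = FALSE)
    vals[r, ] <- v
  }
  colnames(vals) <- header
  out <- tibble::tibble(time = vals[, "time_s"],
                        x = vals[, "x_um"], y = vals[, "y_um"])
  dts <- diff(out$time)
  if (any(dts <= 0)) {
    bad <- lineno[-1L][which(dts <= 0)[1L] + 1L]
    stop("line ", bad, ": time is not strictly increasing", call. = FALSE)
  }
  as_trajectory(out)
}

#' Write a trajectory file
#'
#' Writes the tab-separated format read by [read_trajectory()], with a
#' comment header recording provenance (seed/config hash if supplied).
#' Positions are written with 15 significant digits so a write-read round
#' trip is faithful.
#'
#' @param data A trajectory tibble.
#' @param path Output path.
#' @param comment Optional character vector of comment lines (without
#'   the leading `#`).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(data, path, comment = NULL) {
  data <- as_trajectory(data)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines("time_s\tx_um\ty_um", con)
  writeLines(sprintf("%.15g\t%.15g\t%.15g", data$time, data$x, data$y), con)
  invisible(path)
}

#' Run configuration
#'
#' Collects every tunable of a simulate-fit-profile run with the package
#' defaults: 5 chains of 2000 sweeps with a 1000-sweep burn-in, PSRF
#' threshold 1.2 with a 4e5-sweep cap, state threshold 0.5, minimum event
#' duration 0.01 s for shape analysis, and a 30 nm repeat-site radius.
#'
#' @param chains,n_sweeps,burn_in MCMC run shape.
#' @param psrf_threshold,max_sweeps Convergence protocol.
#' @param subsample_factor Decimation applied before fitting.
#' @param state_threshold Posterior probability cut for confinement.
#' @param min_event_lifetime Minimum duration for shape statistics, s.
#' @param repeat_radius Repeat-site radius, um.
#' @param seed Integer seed.
#' @return A list of class `hpw_run_config`.
#' @export
hpw_run_config <- function(chains = 5, n_sweeps = 2000, burn_in = 1000,
                           psrf_threshold = 1.2, max_sweeps = 4e5,
                           subsample_factor = 1, state_threshold = 0.5,
                           min_event_lifetime = 0.01, repeat_radius = 0.03,
                           seed = 1L) {
  structure(
    list(chains = chains, n_sweeps = n_sweeps, burn_in = burn_in,
         psrf_threshold = psrf_threshold, max_sweeps = max_sweeps,
         subsample_factor = subsample_factor,
         state_threshold = state_threshold,
         min_event_lifetime = min_event_lifetime,
         repeat_radius = repeat_radius, seed = seed),
    class = "hpw_run_config"
  )
}

#' Read or write a run configuration as YAML
#'
#' @param path File path.
#' @return For `read_run_config`, an `hpw_run_config`; the writer returns
#'   `path` invisibly.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- hpw_run_config()
  unknown <- setdiff(names(vals), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(vals)] <- vals
  class(cfg) <- "hpw_run_config"
  cfg
}

#' @rdname read_run_config
#' @param config An `hpw_run_config` object.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "hpw_run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
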