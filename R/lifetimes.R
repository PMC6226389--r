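# Waiting-time analysis of event lifetimes: maximum-likelihood exponential
# and exponential-mixture fits (EM) and quantile-quantile goodness of fit.

#' Fit an exponential or two-exponential mixture to lifetimes
#'
#' One component: the MLE is the sample mean (closed form). Two
#' components: maximum likelihood by expectation-maximization, run from
#' `n_restarts` random initializations and keeping the best, with
#' components reported in increasing order of mean. A mixture with a short
#' and a long mean lifetime indicates a heterogeneous event population,
#' i.e. departures from simple first-order switching kinetics.
#'
#' @param lifetimes Positive waiting times, seconds (at least 10).
#' @param n_components 1 or 2.
#' @param n_restarts Random EM restarts for the 2-component fit.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Iteration cap per restart.
#' @return A list of class `exp_mixture`: `means`, `weights` (sorted by
#'   mean), `loglik`, `n_components`, `n`.
#' @examples
#' set.seed(1)
#' x <- c(rexp(800, 1 / 0.004), rexp(200, 1 / 0.1))
#' fit_exponential_mixture(x, 2)
#' @export
fit_exponential_mixture <- function(lifetimes, n_components = 2,
                                    n_restarts = 20, tol = 1e-8,
                                    max_iter = 2000) {
  if (!is.numeric(lifetimes) || anyNA(lifetimes) || any(lifetimes <= 0))
    stop("`lifetimes` must be positive and finite", call. = FALSE)
  n <- length(lifetimes)
  if (n < 10L) stop("need at least 10 lifetimes", call. = FALSE)
  stopifnot(n_components %in% c(1, 2))

  if (n_components == 1) {
    mu <- mean(lifetimes)
    return(structure(
      list(means = mu, weights = 1,
           loglik = sum(dexp(lifetimes, 1 / mu, log = TRUE)),
           n_components = 1L, n = n),
      class = "exp_mixture"
    ))
  }

  em_once <- function(mu, w) {
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      # E-step in logs to avoid underflow on very short lifetimes
      l1 <- log(w) + dexp(lifetimes, 1 / mu[1], log = TRUE)
      l2 <- log1p(-w) + dexp(lifetimes, 1 / mu[2], log = TRUE)
      mx <- pmax(l1, l2)
      den <- mx + log(exp(l1 - mx) + exp(l2 - mx))
      g1 <- exp(l1 - den)
      ll <- sum(den)
      s1 <- sum(g1)
      if (s1 < 1e-12 || n - s1 < 1e-12) break  # a weight collapsed
      w <- s1 / n
      mu <- c(sum(g1 * lifetimes) / s1, sum((1 - g1) * lifetimes) / (n - s1))
      if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll)) break
      ll_old <- ll
    }
    # report the log-likelihood at the final parameter values
    l1 <- log(w) + dexp(lifetimes, 1 / mu[1], log = TRUE)
    l2 <- log1p(-w) + dexp(lifetimes, 1 / mu[2], log = TRUE)
    mx <- pmax(l1, l2)
    list(mu = mu, w = w, ll = sum(mx + log(exp(l1 - mx) + exp(l2 - mx))))
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    q <- sort(runif(2, 0.05, 0.95))
    mu0 <- unname(quantile(lifetimes, q))
    if (mu0[2] <= mu0[1]) mu0[2] <- mu0[1] * 2
    res <- em_once(mu0, runif(1, 0.2, 0.8))
    if (is.null(best) || res$ll > best$ll) best <- res
  }
  # the one-component solution is nested (equal means); never fall below it
  mu1 <- mean(lifetimes)
  ll1 <- sum(dexp(lifetimes, 1 / mu1, log = TRUE))
  if (!is.finite(best$ll) || best$ll < ll1)
    best <- list(mu = c(mu1, mu1), w = 0.5, ll = ll1)
  ord <- order(best$mu)
  structure(
    list(means = best$mu[ord], weights = c(best$w, 1 - best$w)[ord],
         loglik = best$ll, n_components = 2L, n = n),
    class = "exp_mixture"
  )
}

#' @export
print.exp_mixture <- function(x, ...) {
  cat(sprintf("<exp_mixture> %d component(s), n = %d, logLik = %.2f\n",
              x$n_components, x$n, x$loglik))
  for (k in seq_len(x$n_components))
    cat(sprintf("  mean = %.4g s  weight = %.3f\n", x$means[k], x$weights[k]))
  invisible(x)
}

#' @export
tidy.exp_mixture <- function(x, ...) {
  tibble::tibble(component = seq_len(x$n_components),
                 mean = x$means, weight = x$weights)
}

#' @export
glance.exp_mixture <- function(x, ...) {
  tibble::tibble(n_components = x$n_components, n = x$n, loglik = x$loglik)
}

#' Draw samples from a fitted exponential mixture
#'
#' @param x An `exp_mixture` object.
#' @param n Number of samples.
#' @return Numeric vector of length `n`.
#' @export
rexp_mixture <- function(x, n) {
  stopifnot(inherits(x, "exp_mixture"))
  comp <- sample.int(x$n_components, n, replace = TRUE, prob = x$weights)
  rexp(n, 1 / x$means[comp])
}

#' Quantile-quantile R-squared against a reference distribution
#'
#' Compares the order statistics of the data against reference quantiles
#' (either a reference sample of the same role or a quantile function).
#' The reference line is drawn through the first- and third-quartile
#' points, and R-squared is computed about that line:
#' `1 - SS_resid / SS_total`. A gross misfit (heavy upper tail against a
#' single exponential, say) can push R-squared to or below zero.
#'
#' @param x Observed values (at least 10, non-constant).
#' @param reference Either a numeric vector (a reference sample) or a
#'   quantile function such as `function(p) qexp(p, rate)`.
#' @return A list: `r_squared`, `slope`, `intercept`, and the matched
#'   quantile tibble `points` (columns `theoretical`, `observed`).
#' @examples
#' set.seed(1)
#' qq_r_squared(rexp(500, 2), function(p) qexp(p, 2))$r_squared
#' @export
qq_r_squared <- function(x, reference) {
  if (!is.numeric(x) || length(x) < 10L)
    stop("need at least 10 observations", call. = FALSE)
  if (sd(x) == 0) stop("degenerate (constant) data", call. = FALSE)
  obs <- sort(x)
  p <- (seq_along(obs) - 0.5) / length(obs)
  theo <- if (is.function(reference)) {
    reference(p)
  } else if (is.numeric(reference)) {
    unname(quantile(reference, probs = p, type = 7))
  } else stop("`reference` must be a numeric sample or a quantile function",
              call. = FALSE)

  # line through the first- and third-quartile points
  qo <- unname(quantile(obs, c(0.25, 0.75)))
  qt <- if (is.function(reference)) reference(c(0.25, 0.75)) else
    unname(quantile(reference, c(0.25, 0.75), type = 7))
  if (qt[2] == qt[1]) stop("degenerate reference quartiles", call. = FALSE)
  slope <- (qo[2] - qo[1]) / (qt[2] - qt[1])
  intercept <- qo[1] - slope * qt[1]

  fitted <- intercept + slope * theo
  r2 <- 1 - sum((obs - fitted)^2) / sum((obs - mean(obs))^2)
  list(r_squared = r2, slope = slope, intercept = intercept,
       points = tibble::tibble(theoretical = theo, observed = obs))
}
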