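# Small hand-built fixtures shared across test files.

# A 5-frame trajectory with a mixed hidden path, built by hand so that
# brute-force oracles can be computed scalar by scalar.
tiny_instance <- function() {
  traj <- tibble::tibble(
    time = c(0, 2e-4, 4e-4, 6e-4, 8e-4),
    x = c(0.00, 0.01, 0.005, 0.012, 0.020),
    y = c(0.00, -0.004, 0.002, -0.001, 0.008)
  )
  path <- tibble::tibble(
    state = c(0L, 1L, 1L, 0L),
    cx = c(0.002, 0.006, 0.007, 0.009),
    cy = c(0.001, -0.002, 0.000, 0.003)
  )
  params <- hpw_params(D = 0.5, DC = 0.01, kappa = 3000,
                       p_esc = 0.001, p_trap = 0.002, Dest = 0.5)
  list(traj = traj, path = path, params = params)
}

# Reference per-coordinate Gaussian log-density written independently of
# the package's dnorm-based implementations.
ref_lognorm <- function(v, mean, var) {
  -0.5 * log(2 * pi * var) - (v - mean)^2 / (2 * var)
}

expect_rel_equal <- function(actual, expected, tol) {
  testthat::expect_lt(abs(actual - expected) / max(abs(expected), 1e-12), tol)
}
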