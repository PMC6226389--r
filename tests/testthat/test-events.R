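# Event machinery: thresholding, run extraction, lifetimes, shapes,
# repeats, local diffusivity.

test_that("thresholding uses 0.5 with ties classified free", {
  expect_equal(threshold_states(c(0.1, 0.9, 0.95, 0.2)), c(0L, 1L, 1L, 0L))
  expect_equal(threshold_states(rep(0.5, 4)), rep(0L, 4))
  expect_error(threshold_states(c(0.2, 1.3)), "probabilities")
  expect_equal(state_uncertainty_fraction(c(0.1, 0.5, 0.79, 0.95)), 0.5)
})

test_that("maximal runs become events with boundary flags", {
  times <- seq(0, 1.2, by = 0.2)
  ev <- extract_events(c(0, 1, 1, 0, 0, 1), times)
  conf <- ev[ev$state == "confined", ]
  expect_equal(nrow(conf), 2)
  expect_equal(conf$start_frame, c(2, 6))
  expect_equal(conf$end_frame, c(3, 6))
  expect_equal(conf$touches_boundary, c(FALSE, TRUE))
  expect_equal(nrow(ev[ev$state == "free", ]), 2)

  all1 <- extract_events(rep(1, 5), seq(0, 1, by = 0.2))
  expect_equal(nrow(all1), 1)
  expect_true(all1$touches_boundary)
  expect_equal(all1$lifetime, 1)
})

test_that("event counts obey the transition-count identity", {
  set.seed(1)
  for (k in 1:200) {
    m <- sample(2:40, 1)
    z <- sample(0:1, m, replace = TRUE)
    ev <- extract_events(z, seq_len(m + 1))
    n_conf <- sum(ev$state == "confined")
    expect_equal(n_conf, sum(z[-m] == 0 & z[-1] == 1) + (z[1] == 1))
  }
})

test_that("events partition the increments and lifetimes sum to the duration", {
  set.seed(2)
  m <- 500
  z <- sample(0:1, m, replace = TRUE, prob = c(0.7, 0.3))
  times <- (0:m) * 2e-4
  ev <- extract_events(z, times)
  expect_equal(sum(ev$end_frame - ev$start_frame + 1), m)
  expect_equal(sum(ev$lifetime), times[m + 1] - times[1])
})

test_that("lifetime filtering follows the boundary and duration rules", {
  times <- (0:99) * 2e-4
  z <- rep(0, 99)
  z[1:10] <- 1    # touches start
  z[30:79] <- 1   # 50 increments -> exactly 0.01 s
  z[90:95] <- 1
  ev <- extract_events(z, times)
  lt <- lifetime_table(ev, exclude_boundary = TRUE)
  expect_equal(length(lt), 2)
  kept <- lifetime_table(ev, exclude_boundary = TRUE, min_lifetime = 0.01)
  expect_equal(kept, 0.01)  # the 50-frame event sits exactly on the cut
  expect_equal(length(lifetime_table(ev[0, ])), 0)
})

test_that("shape statistics match a spreadsheet computation on 5 points", {
  x <- c(0.010, 0.013, 0.007, 0.011, 0.009)
  y <- c(0.002, -0.001, 0.004, 0.000, 0.003)
  cx <- 0.010; cy <- 0.001
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  s <- shape_statistics(x, y, cx, cy)
  expect_equal(s$mean_radius, mean(r))
  m2 <- mean((r - mean(r))^2)
  expect_equal(s$radial_sd, sqrt(m2))
  expect_equal(s$radial_var, m2)
  expect_equal(s$radial_skewness, mean((r - mean(r))^3) / m2^1.5)
  expect_equal(s$mean_median_distance, abs(mean(r) - median(r)))
})

test_that("a degenerate ring reports zero spread and flagged skewness", {
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  s <- shape_statistics(cos(th) * 0.01, sin(th) * 0.01, 0, 0)
  expect_equal(s$mean_radius, 0.01)
  expect_equal(s$radial_sd, 0, tolerance = 1e-12)
  expect_equal(s$radial_skewness, 0)
  expect_true(s$degenerate)
  expect_error(shape_statistics(1, 1, 0, 0), "at least 2")
})

test_that("shape statistics are rotation and translation invariant", {
  set.seed(3)
  x <- rnorm(50, 0, 0.01); y <- rnorm(50, 0, 0.01)
  s0 <- shape_statistics(x, y, 0.001, -0.002)
  th <- 0.83
  xr <- cos(th) * (x + 5) - sin(th) * (y - 2)
  yr <- sin(th) * (x + 5) + cos(th) * (y - 2)
  cr <- c(cos(th) * (0.001 + 5) - sin(th) * (-0.002 - 2),
          sin(th) * (0.001 + 5) + cos(th) * (-0.002 - 2))
  s1 <- shape_statistics(xr, yr, cr[1], cr[2])
  for (cl in c("mean_radius", "radial_skewness", "mean_median_distance",
               "radial_sd")) {
    expect_equal(s1[[cl]], s0[[cl]], tolerance = 1e-9)
  }
})

test_that("the radial skewness of Gaussian confinement approaches 0.63", {
  set.seed(4)
  n <- 1e6
  s <- shape_statistics(rnorm(n, 3, 0.02), rnorm(n, -1, 0.02), 3, -1)
  rayleigh_skew <- 2 * sqrt(pi) * (pi - 3) / (4 - pi)^1.5
  expect_lt(abs(s$radial_skewness - rayleigh_skew), 0.01)
})

test_that("repeat-site detection uses the 30 nm any-earlier rule", {
  ev <- tibble::tibble(id = "t1",
                       cx_bar = c(0, 0.010, 0.045),
                       cy_bar = c(0, 0, 0))
  out <- mark_repeats(ev)
  expect_equal(out$is_repeat, c(FALSE, TRUE, FALSE))

  far <- tibble::tibble(id = "t1", cx_bar = c(0, 0.040), cy_bar = c(0, 0))
  expect_equal(mark_repeats(far)$is_repeat, c(FALSE, FALSE))

  # chain: B within 25 nm of A; C within 25 nm of B but 50 nm from A
  chain <- tibble::tibble(id = "t1",
                          cx_bar = c(0, 0.025, 0.050), cy_bar = c(0, 0, 0))
  expect_equal(mark_repeats(chain)$is_repeat, c(FALSE, TRUE, TRUE))

  # repeats never cross trajectories
  two <- tibble::tibble(id = c("t1", "t2"), cx_bar = c(0, 0.001),
                        cy_bar = c(0, 0))
  expect_equal(mark_repeats(two)$is_repeat, c(FALSE, FALSE))
})

test_that("local diffusivity estimates Brownian motion without bias", {
  set.seed(5)
  n <- 1e4; dt <- 2e-4; D <- 0.5
  traj <- tibble::tibble(time = (seq_len(n) - 1) * dt,
                         x = cumsum(c(0, rnorm(n - 1, 0, sqrt(2 * D * dt)))),
                         y = cumsum(c(0, rnorm(n - 1, 0, sqrt(2 * D * dt)))))
  ld <- local_diffusivity(traj, window = 100)$D_local
  se <- D / sqrt(2 * (n - 1))   # pooled-estimate error scale
  expect_lt(abs(mean(ld) - D), 3 * se * sqrt(50))  # windows overlap heavily
  frozen <- tibble::tibble(time = traj$time, x = rep(1, n), y = rep(2, n))
  expect_true(all(local_diffusivity(frozen, 100)$D_local == 0))
})

test_that("local diffusivity drops inside confinement events", {
  sim <- simulate_hpw(n_frames = 2e4, seed = 6)
  z <- sim$state[-nrow(sim)]
  ld <- local_diffusivity(sim, window = 100)$D_local[seq_along(z)]
  expect_lt(mean(ld[z == 1]), mean(ld[z == 0]))
})

test_that("profile_events assembles the event table end to end", {
  sim <- simulate_hpw(n_frames = 4000, seed = 8)
  fit <- run_hpw(sim, chains = 2, n_sweeps = 500, burn_in = 250, seed = 9)
  ev <- profile_events(fit, id = "sim1")
  expect_true(all(c("lifetime", "touches_boundary", "cx_bar", "cy_bar",
                    "mean_radius", "radial_skewness", "is_repeat") %in%
                    names(ev)))
  if (nrow(ev) > 0) {
    expect_true(all(ev$lifetime > 0))
    long <- ev[ev$lifetime >= 0.01, ]
    if (nrow(long) > 0) expect_true(all(is.finite(long$mean_radius)))
  }
})
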