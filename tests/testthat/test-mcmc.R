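# MCMC conditional updates against independent oracles, plus the run
# contract of the chain driver.

make_small_traj <- function(n, seed = 1, dt = 2e-4) {
  set.seed(seed)
  tibble::tibble(time = (seq_len(n) - 1) * dt,
                 x = cumsum(c(0, rnorm(n - 1, 0, 0.01))),
                 y = cumsum(c(0, rnorm(n - 1, 0, 0.01))))
}

test_that("state sampler matches exhaustive path enumeration", {
  traj <- make_small_traj(4, seed = 42)
  centers <- tibble::tibble(cx = c(0.002, -0.003, 0.004),
                            cy = c(0.001, 0.002, -0.001))
  p <- hpw_params(D = 0.3, DC = 0.02, kappa = 2000,
                  p_esc = 0.2, p_trap = 0.3, Dest = 0.3)

  # independent oracle: enumerate all 2^3 paths with hand-written densities
  dt <- diff(traj$time)
  a <- 1 - exp(-p$kappa * dt)
  vconf <- (p$D / p$kappa) * (1 - exp(-2 * p$kappa * dt))
  vfree <- 2 * p$D * dt
  logemit <- function(i, z) {
    mx <- if (z == 1) (centers$cx[i] - traj$x[i]) * a[i] else 0
    my <- if (z == 1) (centers$cy[i] - traj$y[i]) * a[i] else 0
    v <- if (z == 1) vconf[i] else vfree[i]
    out <- ref_lognorm(traj$x[i + 1] - traj$x[i], mx, v) +
      ref_lognorm(traj$y[i + 1] - traj$y[i], my, v)
    if (i < 3) {
      vc <- 2 * dt[i] * if (z == 1) p$DC else p$Dest
      out <- out + ref_lognorm(centers$cx[i + 1] - centers$cx[i], 0, vc) +
        ref_lognorm(centers$cy[i + 1] - centers$cy[i], 0, vc)
    }
    out
  }
  paths <- as.matrix(expand.grid(z1 = 0:1, z2 = 0:1, z3 = 0:1))
  logw <- apply(paths, 1, function(z) {
    lw <- log(0.5)
    for (i in 1:3) lw <- lw + logemit(i, z[i])
    for (i in 1:2) {
      p1 <- z[i] * (1 - p$p_esc) + (1 - z[i]) * p$p_trap
      lw <- lw + log(if (z[i + 1] == 1) p1 else 1 - p1)
    }
    lw
  })
  w <- exp(logw - max(logw)); w <- w / sum(w)

  set.seed(31)
  n_draw <- 1e5
  draws <- replicate(n_draw, sample_states(traj, centers, p))
  key <- apply(draws, 2, paste, collapse = "")
  freq <- table(factor(key, levels = apply(paths, 1, paste, collapse = "")))
  tv <- 0.5 * sum(abs(as.numeric(freq) / n_draw - w))
  expect_lt(tv, 0.01)
})

test_that("state sampler is symmetric when emissions carry no information", {
  set.seed(4)
  m <- 50
  logf <- rnorm(m)
  draws <- replicate(2000, hpwtrack:::ffbs_binary_cpp(logf, logf, 0.3, 0.3, 0.5))
  marg <- rowMeans(draws)
  expect_true(all(abs(marg - 0.5) < 4 * sqrt(0.25 / 2000)))
})

test_that("center sampler with no observations is a free random walk", {
  traj <- make_small_traj(300, seed = 5)
  p <- hpw_params(D = 0.5, DC = 0.01, kappa = 3000,
                  p_esc = 0.01, p_trap = 0.01, Dest = 0.4)
  set.seed(6)
  cs <- sample_centers(traj, rep(0L, 299), p)
  v <- var(c(diff(cs$cx), diff(cs$cy)))
  target <- 2 * p$Dest * 2e-4
  expect_lt(abs(v - target), 4 * sqrt(2 / (2 * 298)) * target)
})

test_that("static-center posterior matches the conjugate Gaussian product", {
  # all confined, DC -> 0: one static center observed through each increment
  n <- 40
  traj <- make_small_traj(n, seed = 7)
  p <- hpw_params(D = 0.5, DC = 1e-10, kappa = 3000,
                  p_esc = 0.01, p_trap = 0.01, Dest = 0.5)
  dt <- diff(traj$time)
  a <- 1 - exp(-p$kappa * dt)
  v <- (p$D / p$kappa) * (1 - exp(-2 * p$kappa * dt))
  m <- n - 1L
  i <- seq_len(m)
  yobs <- traj$x[i] + diff(traj$x) / a
  robs <- v / a^2
  # conjugate product with the diffuse N(x_1, 100) prior on the center
  prec <- 1 / 100 + sum(1 / robs)
  mean_post <- (traj$x[1] / 100 + sum(yobs / robs)) / prec
  set.seed(8)
  draws <- replicate(4000, sample_centers(traj, rep(1L, m), p)$cx[1])
  expect_lt(abs(mean(draws) - mean_post), 4 * sd(draws) / sqrt(4000))
  expect_lt(abs(var(draws) - 1 / prec) / (1 / prec), 0.15)
})

test_that("center sampler matches a dense joint-Gaussian oracle on a mixed path", {
  n <- 5
  traj <- make_small_traj(n, seed = 9)
  z <- c(1L, 0L, 1L, 1L)
  p <- hpw_params(D = 0.4, DC = 0.05, kappa = 1500,
                  p_esc = 0.01, p_trap = 0.01, Dest = 0.6)
  m <- n - 1L
  dt <- diff(traj$time)
  a <- 1 - exp(-p$kappa * dt)
  v <- (p$D / p$kappa) * (1 - exp(-2 * p$kappa * dt))

  # dense construction: prior covariance of the center path, then
  # condition on the pseudo-observations of the confined increments
  q <- 2 * dt[1:(m - 1)] * ifelse(z[1:(m - 1)] == 1, p$DC, p$Dest)
  L <- matrix(0, m, m)
  L[1, 1] <- sqrt(100)
  mu <- rep(traj$x[1], m)
  for (t in 2:m) { L[t, ] <- L[t - 1, ]; L[t, t] <- sqrt(q[t - 1]) }
  S <- L %*% t(L)
  obs <- which(z == 1L)
  H <- diag(m)[obs, , drop = FALSE]
  R <- diag(v[obs] / a[obs]^2, length(obs))
  y <- (traj$x[obs] + diff(traj$x)[obs] / a[obs])
  K <- S %*% t(H) %*% solve(H %*% S %*% t(H) + R)
  post_mu <- mu + as.vector(K %*% (y - H %*% mu))
  post_S <- S - K %*% H %*% S

  set.seed(10)
  draws <- t(replicate(20000, sample_centers(traj, z, p)$cx))
  expect_true(all(abs(colMeans(draws) - post_mu) <
                    4 * sqrt(diag(post_S) / 20000)))
  expect_true(all(abs(apply(draws, 2, var) - diag(post_S)) /
                    diag(post_S) < 0.1))
  expect_lt(abs(cov(draws[, 1], draws[, 2]) - post_S[1, 2]) /
              abs(post_S[1, 2]), 0.1)
})

test_that("free-trajectory D conditional is the closed-form inverse gamma", {
  n <- 200
  traj <- make_small_traj(n, seed = 11)
  priors <- hpw_priors()
  m <- n - 1L
  dt <- diff(traj$time)
  shape <- priors$D_shape + m
  rate <- priors$D_rate +
    sum((diff(traj$x)^2 + diff(traj$y)^2) / (4 * dt))
  centers <- tibble::tibble(cx = rep(0, m), cy = rep(0, m))
  set.seed(12)
  draws <- vapply(1:5000, function(k) {
    sample_diffusivities(traj, rep(0L, m), centers, 3000, priors)$D
  }, numeric(1))
  ks <- ks.test(draws, function(q) 1 - pgamma(1 / q, shape, rate = rate))
  expect_gt(ks$p.value, 0.01)
})

test_that("doubling displacements quadruples the posterior mean of D", {
  n <- 400
  traj <- make_small_traj(n, seed = 13)
  big <- traj; big$x <- big$x * 2; big$y <- big$y * 2
  priors <- hpw_priors()
  m <- n - 1L
  centers <- tibble::tibble(cx = rep(0, m), cy = rep(0, m))
  set.seed(14)
  d1 <- mean(vapply(1:4000, function(k)
    sample_diffusivities(traj, rep(0L, m), centers, 3000, priors)$D,
    numeric(1)))
  d2 <- mean(vapply(1:4000, function(k)
    sample_diffusivities(big, rep(0L, m), centers, 3000, priors)$D,
    numeric(1)))
  expect_equal(d2 / d1, 4, tolerance = 0.05)
})

test_that("switching conditional reproduces the hand-counted Beta laws", {
  z <- c(0L, 0L, 1L, 1L, 1L)
  priors <- hpw_priors(switch_a = 1, switch_b = 1)
  # transitions: 0->0 once, 0->1 once, 1->1 twice, 1->0 none
  set.seed(15)
  draws <- replicate(5000, unlist(sample_switching(z, priors)))
  expect_gt(ks.test(draws["p_trap", ], function(q) pbeta(q, 2, 2))$p.value, 0.01)
  expect_gt(ks.test(draws["p_esc", ], function(q) pbeta(q, 1, 3))$p.value, 0.01)
})

test_that("an informative switching prior dominates without transitions", {
  z <- rep(1L, 100)   # no transitions out; n11 = 99
  priors <- hpw_priors(switch_a = 1, switch_b = 50)
  set.seed(16)
  pt <- replicate(3000, sample_switching(z, priors)$p_trap)
  # p_trap posterior = prior Beta(1, 50) since no 0-state time observed
  expect_gt(ks.test(pt, function(q) pbeta(q, 1, 50))$p.value, 0.01)
})

test_that("kappa sampler reproduces its log-uniform prior without data", {
  traj <- make_small_traj(10, seed = 17)
  priors <- hpw_priors(kappa_min = 1, kappa_max = 1e6)
  centers <- tibble::tibble(cx = rep(0, 9), cy = rep(0, 9))
  set.seed(18)
  # no confined increments: the update draws straight from the prior
  draws <- vapply(1:10000, function(k) {
    sample_kappa(traj, rep(0L, 9), centers, 0.5, 100, priors)$kappa
  }, numeric(1))
  ks <- ks.test(log(draws), "punif", log(1), log(1e6))
  expect_gt(ks$p.value, 0.01)
})

test_that("chains are bitwise reproducible given the seed", {
  sim <- simulate_hpw(n_frames = 300, seed = 20)
  f1 <- run_hpw(sim, chains = 2, n_sweeps = 120, burn_in = 60, seed = 5)
  f2 <- run_hpw(sim, chains = 2, n_sweeps = 120, burn_in = 60, seed = 5)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$state_prob, f2$state_prob)
})

test_that("degenerate trajectories are rejected with a clean error", {
  tiny <- tibble::tibble(time = c(0, 1e-3), x = c(0, 0.1), y = c(0, 0))
  expect_error(run_hpw(tiny), "at least 3 frames")
})
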