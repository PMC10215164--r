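test_that("bin grids enumerate the simplex-interior index pairs", {
  expect_equal(build_bin_grid(1)$m, 1L)
  expect_equal(build_bin_grid(0.05)$m, 210L)
  g <- build_bin_grid(0.5)
  expect_equal(g$m, 3L)
  expect_equal(g$bins$i, c(0L, 0L, 1L))
  expect_equal(g$bins$j, c(0L, 1L, 0L))
  expect_equal(g$bins$x_center, c(0.25, 0.25, 0.75))
  # the defining invariant: i + j <= ceil(1/h) - 1
  g2 <- build_bin_grid(0.2)
  expect_true(all(g2$bins$i + g2$bins$j <= ceiling(1 / 0.2) - 1))
  expect_equal(g2$m, 15L)
  expect_error(build_bin_grid(0), "'h'")
  expect_error(build_bin_grid(1.2), "'h'")
})

test_that("bin membership is half-open with boundary handling", {
  g <- build_bin_grid(0.05)
  b <- g$bins
  k <- bin_of(0.0, 0.0, g)
  expect_equal(c(b$i[k], b$j[k]), c(0L, 0L))
  k <- bin_of(0.05, 0.0, g)  # left edges belong to the higher bin
  expect_equal(b$i[k], 1L)
  k <- bin_of(1, 0, g)       # traits exactly at 1 fall to the last bin
  expect_equal(b$i[k], 19L)
  k <- bin_of(0.5, 0.5, g)   # hypotenuse point pushed inside the simplex
  expect_equal(b$i[k] + b$j[k], 19L)
  expect_true(all(bin_of(runif(50, 0, 0.5), runif(50, 0, 0.5), g) >= 1))
})

test_that("action realization matches the chosen bin when noise-free", {
  g <- build_bin_grid(0.05)
  probs <- rep(0, g$m); probs[37] <- 1
  set.seed(8)
  r <- realize_action(probs, g, jitter_sigma = 0)
  expect_equal(r$chosen, 37L)
  expect_equal(r$realized, 37L)
  expect_equal(r$x, g$bins$x_center[37])
  expect_equal(r$y, g$bins$y_center[37])
  expect_error(realize_action(rep(0, g$m), g, 0), "probs")
})

test_that("bin-escape frequency matches the integrated Gaussian mass", {
  g <- build_bin_grid(0.05)
  # a central bin far from all boundaries
  a <- which(g$bins$i == 6 & g$bins$j == 6)
  cx <- g$bins$x_center[a]; cy <- g$bins$y_center[a]
  sigma <- 0.05
  p_in_axis <- function(lo, hi, c0) pnorm(hi, c0, sigma) - pnorm(lo, c0, sigma)
  p_stay <- p_in_axis(g$bins$x_lo[a], g$bins$x_hi[a], cx) *
    p_in_axis(g$bins$y_lo[a], g$bins$y_hi[a], cy)
  probs <- rep(0, g$m); probs[a] <- 1
  set.seed(9)
  esc <- mean(replicate(20000,
                        realize_action(probs, g, sigma)$realized != a))
  expect_equal(esc, 1 - p_stay, tolerance = 0.01 / (1 - p_stay))
})

test_that("payoff normalisation is the clipped affine map", {
  b <- c(min = -2, max = 6)
  expect_equal(normalize_payoff(-2, b), 0)
  expect_equal(normalize_payoff(6, b), 1)
  expect_equal(normalize_payoff(2, b), 0.5)
  expect_equal(normalize_payoff(c(-5, 10), b), c(0, 1))
  expect_error(normalize_payoff(1, c(min = 3, max = 3)), "degenerate")
})

test_that("the cross rule reinforces, conserves, and has its fixed points", {
  expect_equal(cross_update(c(0.5, 0.5), 1, 1, 0.01), c(0.505, 0.495))
  p <- c(0.2, 0.3, 0.5)
  expect_equal(cross_update(p, 2, 0, 0.5), p)
  pure <- c(0, 1, 0)
  expect_equal(cross_update(pure, 2, 0.8, 0.3), pure)
  expect_error(cross_update(p, 2, 1.5, 0.1), "pi_hat")
  expect_error(cross_update(p, 5, 0.5, 0.1), "realized")
})

test_that("cross updates conserve probability over random cases", {
  set.seed(10)
  for (r in 1:2000) {
    m <- sample(2:210, 1)
    p <- runif(m); p <- p / sum(p)
    out <- cross_update(p, sample(m, 1), runif(1), runif(1, 1e-6, 1))
    expect_true(abs(sum(out) - 1) <= 1e-12)
    expect_true(min(out) >= 0)
  }
})

test_that("expected one-step cross motion equals the replicator increment", {
  # single learner, two actions with fixed payoffs: brute force over both
  # outcomes against alpha * p1 * (1 - p1) * (u1 - u2)
  alpha <- 0.17
  for (p1 in seq(0.1, 0.9, by = 0.2)) {
    for (u1 in c(0, 0.35, 1)) for (u2 in c(0.1, 0.8)) {
      d1 <- cross_update(c(p1, 1 - p1), 1, u1, alpha)[1] - p1
      d2 <- cross_update(c(p1, 1 - p1), 2, u2, alpha)[1] - p1
      expected <- p1 * d1 + (1 - p1) * d2
      expect_equal(expected, alpha * p1 * (1 - p1) * (u1 - u2),
                   tolerance = 1e-12)
    }
  }
})

test_that("cross-learning runs are reproducible and well-formed", {
  env <- dol_env_preset("uniform")
  cfg <- cross_config(N = 20, T = 200, thin = 20)
  t1 <- run_individual(cfg, env, seed = 21)
  t2 <- run_individual(cfg, env, seed = 21)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$policy, t2$policy)
  expect_false(identical(t1$x, run_individual(cfg, env, seed = 22)$x))
  # policies remain distributions
  expect_equal(rowSums(t1$policy), rep(1, 20), tolerance = 1e-9)
  expect_true(min(t1$policy) >= 0)
  # realized profiles live on the simplex
  expect_true(all(t1$x >= 0 & t1$y >= 0 & t1$x + t1$y <= 1 + 1e-12))
  # mean realized strategy is in the simplex at every stored generation
  mt <- mean_trait_trajectory(t1)
  expect_true(all(mt$x >= 0 & mt$y >= 0 & mt$x + mt$y <= 1 + 1e-12))
  # single-generation run stores exactly the initial realized profile
  t0 <- run_individual(cross_config(N = 20, T = 1), env, seed = 5)
  expect_equal(t0$generation, 0L)
})

test_that("payoffs recorded for a snapshot match the environment formulas", {
  # the compiled kernel's payoff arithmetic against the R implementation,
  # on a noise-free monomorphic generation
  env <- dol_env_preset("branching")
  cfg <- social_config(N = 10, T = 1, x0 = 0.3, y0 = 0.6,
                       store_payoffs = TRUE)
  t1 <- run_social(cfg, env, seed = 2)
  expect_equal(as.numeric(t1$payoff[1, ]),
               rep(payoff(1, rep(0.3, 5), rep(0.6, 5), env), 10),
               tolerance = 1e-12)
})

test_that("cross-learning config validation catches bad values", {
  expect_error(cross_config(alpha = 0), "'alpha'")
  expect_error(cross_config(alpha = 1.2), "'alpha'")
  expect_error(cross_config(h = 0), "'h'")
  expect_error(cross_config(jitter_sigma = -1), "'jitter_sigma'")
})
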