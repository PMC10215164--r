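test_that("task-X benefit is the quadratic with its hand-computed values", {
  env <- dol_env(b1 = 20, b2 = -4, w = 0.5)
  expect_identical(benefit_task_x(0, env), 0)
  # vertex of the parabola: -b1/(2 b2) = 2.5, value 25
  expect_equal(benefit_task_x(2.5, env), 25)
  expect_equal(benefit_task_x(1, dol_env(b1 = 16, b2 = -6, w = 0.5)), 10)
  expect_error(benefit_task_x(-0.1, env), "collective effort")
  expect_error(benefit_task_x(env$n + 0.1, env), "collective effort")
})

test_that("task-X benefit is concave on a grid when b2 < 0", {
  env <- dol_env(b1 = 16, b2 = -6, w = 0.5)
  vals <- benefit_task_x(seq(0, env$n, by = 0.1), env)
  expect_true(all(diff(diff(vals)) <= 1e-9))
})

test_that("task-Y benefit is the logistic centred at 1/w", {
  expect_equal(benefit_task_y(2, dol_env(b1 = 1, b2 = 0, w = 0.5, beta = 3)),
               0.5)
  expect_equal(benefit_task_y(5, dol_env(b1 = 1, b2 = 0, w = 0.2, beta = 3)),
               0.5)
  # logistic at E = 0 with midpoint 10/3 and slope 3
  env <- dol_env(b1 = 1, b2 = 0, w = 0.3, beta = 3)
  expect_equal(benefit_task_y(0, env), 1 / (1 + exp(3 * (1 / 0.3))),
               tolerance = 1e-12)
  vals <- benefit_task_y(seq(0, 5, by = 0.05), env)
  expect_true(all(diff(vals) > 0))
  # slope at the inflection is beta / 4
  eps <- 1e-6
  slope <- (benefit_task_y(1 / 0.3 + eps, env) -
              benefit_task_y(1 / 0.3 - eps, env)) / (2 * eps)
  expect_equal(slope, 3 / 4, tolerance = 1e-6)
})

test_that("group benefit couples the tasks multiplicatively", {
  env <- dol_env(b1 = 20, b2 = -4, w = 0.5, beta = 3)
  expect_identical(group_benefit(0, 3, env), 0)
  # B_X(2.5) = 25, B_Y(2) = 0.5, n = 5
  expect_equal(group_benefit(2.5, 2, env), 2.5)
})

test_that("individual cost is additive, z-free, and zero at rest", {
  env <- dol_env(b1 = 1, b2 = 0, w = 0.5,
                 cost_coeff_x = 1, cost_exp_x = 0.5,
                 cost_coeff_y = 1, cost_exp_y = 0.5)
  expect_identical(individual_cost(0, 0, env), 0)
  expect_equal(individual_cost(0.25, 0, env), 0.5)
  # same (x, y), different implicit z: identical cost
  expect_equal(individual_cost(0.2, 0.3, env), individual_cost(0.2, 0.3, env))
  expect_equal(individual_cost(0.25, 0.25, env), 0.5 + 0.5)
})

test_that("payoff is shared benefit minus own cost", {
  env0 <- dol_env(b1 = 20, b2 = -4, w = 0.5, beta = 3,
                  cost_coeff_x = 0, cost_coeff_y = 0)
  # monomorphic group at (0.5, 0.4): totals (2.5, 2.0) -> benefit 2.5
  expect_equal(payoff(1, rep(0.5, 5), rep(0.4, 5), env0), 2.5)
  expect_equal(payoff(1, rep(0, 5), rep(0, 5), env0), 0)
  expect_error(payoff(1, rep(0.5, 4), rep(0.4, 4), env0), "exactly n")
  # identical strategies in the same group earn identical payoffs
  env <- dol_env_preset("uniform")
  gx <- c(0.2, 0.2, 0.5, 0.1, 0); gy <- c(0.3, 0.3, 0.2, 0.6, 0.4)
  expect_equal(payoff(1, gx, gy, env), payoff(2, gx, gy, env))
})

test_that("payoff decomposes exactly into benefit and cost", {
  env <- dol_env_preset("branching")
  set.seed(42)
  for (rep in 1:25) {
    gx <- runif(5, 0, 0.5); gy <- runif(5, 0, 0.5)
    p1 <- payoff(3, gx, gy, env)
    expect_equal(p1 + individual_cost(gx[3], gy[3], env) -
                   group_benefit(sum(gx), sum(gy), env), 0,
                 tolerance = 1e-12)
  }
})

test_that("group benefit is exchangeable in the members", {
  env <- dol_env_preset("specialised")
  set.seed(7)
  for (rep in 1:10) {
    gx <- runif(5, 0, 0.5); gy <- runif(5, 0, 0.5)
    perm <- sample(5)
    expect_equal(payoff(1, gx, gy, env),
                 payoff(which(perm == 1), gx[perm], gy[perm], env))
  }
})

test_that("payoff bounds certify the brute-force composition grid", {
  grid <- build_bin_grid(0.05)
  cx <- grid$bins$x_center; cy <- grid$bins$y_center
  for (preset in c("specialised", "branching", "uniform")) {
    env <- dol_env_preset(preset)
    b <- payoff_bounds(env)
    expect_lt(b[["min"]], b[["max"]])
    # monomorphic groups and every single-deviant composition on the grid
    for (k in seq_along(cx)) {
      resx <- cx[k] * (env$n - 1); resy <- cy[k] * (env$n - 1)
      pays <- group_benefit(pmin(resx + cx, env$n),
                            pmin(resy + cy, env$n), env) -
        individual_cost(cx, cy, env)
      expect_true(all(pays >= b[["min"]] - 1e-9))
      expect_true(all(pays <= b[["max"]] + 1e-9))
    }
    # the analytic benefit peak is inside the certified interval
    if (env$b2 < 0) {
      peak <- group_benefit(min(max(-env$b1 / (2 * env$b2), 0), env$n),
                            env$n, env)
      expect_gte(b[["max"]], peak - 1e-9)
      expect_lte(b[["min"]], 0)
    }
  }
})

test_that("strategy constructor enforces the simplex", {
  s <- strategy(c(0.3, 0), c(0.6, 0))
  expect_equal(s$z, c(0.1, 1))
  expect_error(strategy(-0.1, 0.5), "non-negative")
  expect_error(strategy(0.6, 0.6), "x \\+ y")
  expect_error(strategy(NA_real_, 0.5), "NA")
})

test_that("presets carry the published environment parameters", {
  e <- dol_env_preset("branching")
  expect_equal(c(e$b1, e$b2, e$w), c(20, -4, 0.3))
  expect_equal(dol_env_preset("specialised")$b1, 16)
  expect_equal(dol_env_preset("uniform")$w, 0.5)
  expect_equal(e$beta, 3)
  expect_equal(e$n, 5L)
})

test_that("environment validation rejects bad parameters", {
  expect_error(dol_env(b1 = 1, b2 = 0, w = -1), "'w'")
  expect_error(dol_env(b1 = 1, b2 = 0, w = 0.5, n = 1), "'n'")
  expect_error(dol_env(b1 = 1, b2 = 0, w = 0.5, cost_exp_x = 1.5),
               "cost exponents")
  expect_error(dol_env(b1 = 1, b2 = 0, w = 0.5, cost_coeff_x = -1),
               "cost coefficients")
})
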