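test_that("invasion fitness reduces to known closed forms", {
  env <- dol_env_preset("uniform")
  # mutant = resident: the monomorphic payoff
  f <- invasion_fitness(0.3, 0.4, 0.3, 0.4, env)
  expect_equal(f, payoff(1, rep(0.3, 5), rep(0.4, 5), env))
  # a fully inactive world yields zero
  expect_equal(invasion_fitness(0, 0, 0, 0, env), 0)
  # no X-effort anywhere: the mutant can only pay the Y cost
  f0 <- invasion_fitness(0, 0.4, 0, 0, env)
  expect_equal(f0, -individual_cost(0, 0.4, env))
  expect_lte(f0, 0)
})

test_that("selection gradient agrees with an independent difference scheme", {
  # two-step-size oracle over an interior lattice, all three presets
  for (preset in c("specialised", "branching", "uniform")) {
    env <- dol_env_preset(preset)
    s <- seq(0.02, 0.95, length.out = 20)
    worst <- 0
    for (x in s) for (y in s) {
      if (x + y > 0.97) next
      g <- selection_gradient(x, y, env)          # step 1e-6
      h <- 1e-4                                   # independent step
      f <- function(xm, ym) invasion_fitness(xm, ym, x, y, env)
      go <- c((f(x + h, y) - f(x - h, y)) / (2 * h),
              (f(x, y + h) - f(x, y - h)) / (2 * h))
      rel <- sqrt(sum((g - go)^2)) / max(sqrt(sum(go^2)), 1e-8)
      worst <- max(worst, rel)
    }
    expect_lt(worst, 1e-3)
  }
})

test_that("the cost part of the gradient matches the hand derivative", {
  env <- dol_env(b1 = 0, b2 = 0, w = 0.5, cost_coeff_x = 2.1,
                 cost_exp_x = 0.8, cost_coeff_y = 1.5, cost_exp_y = 0.5)
  g <- selection_gradient(0.4, 0.25, env)
  expect_equal(g[["gx"]], -2.1 * 0.8 * 0.4^(-0.2), tolerance = 1e-5)
  expect_equal(g[["gy"]], -1.5 * 0.5 * 0.25^(-0.5), tolerance = 1e-5)
})

test_that("singular points of the presets are found and classified", {
  env_u <- dol_env_preset("uniform")
  pts <- find_singular_points(env_u, n_starts = 20, seed = 1)
  expect_gt(length(pts), 0)
  labs <- vapply(pts, `[[`, character(1), "label")
  expect_true("ESS_stable" %in% labs)
  ess <- pts[[which(labs == "ESS_stable")[1]]]
  expect_lt(ess$gradient_norm, 1e-5)
  expect_gt(ess$z, 0)

  env_b <- dol_env_preset("branching")
  pts_b <- find_singular_points(env_b, n_starts = 20, seed = 1)
  labs_b <- vapply(pts_b, `[[`, character(1), "label")
  expect_true("branching" %in% labs_b)
  bp <- pts_b[[which(labs_b == "branching")[1]]]
  expect_true(all(bp$jacobian_real_parts < 0))       # convergence stable
  expect_gt(max(bp$hessian_eigenvalues), 0)          # but invadable
})

test_that("more starts never lose a previously found root", {
  env <- dol_env_preset("uniform")
  few <- find_singular_points(env, n_starts = 8, seed = 3)
  many <- find_singular_points(env, n_starts = 32, seed = 3)
  for (p in few) {
    d <- vapply(many, function(q) sqrt((p$x - q$x)^2 + (p$y - q$y)^2),
                numeric(1))
    expect_lt(min(d), 1e-3)
  }
})

test_that("classification is stable under step halving", {
  env <- dol_env_preset("branching")
  pts <- find_singular_points(env, n_starts = 15, seed = 2)
  for (p in pts) {
    c1 <- classify_singular_point(p$x, p$y, env, tol = 1e-4, step = 1e-4)
    c2 <- classify_singular_point(p$x, p$y, env, tol = 1e-4, step = 5e-5)
    expect_identical(c1$label, c2$label)
  }
  expect_error(classify_singular_point(0.3, 0.6, env), "not singular")
})

test_that("the vector field respects the simplex and ascends fitness", {
  env <- dol_env_preset("uniform")
  fld <- canonical_vector_field(env, resolution = 12)
  expect_true(all(fld$x + fld$y <= 1))
  eps <- 1e-6
  interior <- fld$x > 0.05 & fld$y > 0.05 & fld$x + fld$y < 0.9
  for (k in which(interior)) {
    gn <- sqrt(fld$gx[k]^2 + fld$gy[k]^2)
    if (gn < 1e-8) next
    f0 <- invasion_fitness(fld$x[k], fld$y[k], fld$x[k], fld$y[k], env)
    f1 <- invasion_fitness(fld$x[k] + eps * fld$gx[k] / gn,
                           fld$y[k] + eps * fld$gy[k] / gn,
                           fld$x[k], fld$y[k], env)
    expect_gte(f1 - f0, -1e-10)
  }
  # the field vanishes at a reported singular point
  pts <- find_singular_points(env, n_starts = 10, seed = 4)
  sp <- pts[[1]]
  expect_lt(sqrt(sum(selection_gradient(sp$x, sp$y, env)^2)), 1e-5)
})

test_that("the gradient flow reproduces the three-regime taxonomy", {
  expect_equal(ad_regime(dol_env_preset("specialised"))$label,
               "fully_specialised")
  expect_equal(ad_regime(dol_env_preset("branching"))$label, "branching")
  expect_equal(ad_regime(dol_env_preset("uniform"))$label, "uniform")
})
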