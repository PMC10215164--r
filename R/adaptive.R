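#' Invasion fitness of a rare mutant
#'
#' Payoff of a lone mutant with traits \code{(x_mut, y_mut)} playing in a
#' group whose other \eqn{n - 1} members are monomorphic residents at
#' \code{(x_res, y_res)}:
#' \deqn{f = B(x' + (n-1)x, \; y' + (n-1)y) - C(x', y').}
#' This is the standard rare-mutant construction of adaptive dynamics for
#' n-player games.
#'
#' @param x_mut,y_mut Mutant traits.
#' @param x_res,y_res Resident traits.
#' @param env A [dol_env()].
#' @return Invasion fitness in payoff units.
#' @export
invasion_fitness <- function(x_mut, y_mut, x_res, y_res, env) {
  check_strategy(x_mut, y_mut)
  check_strategy(x_res, y_res)
  group_benefit(x_mut + (env$n - 1) * x_res,
                y_mut + (env$n - 1) * y_res, env) -
    individual_cost(x_mut, y_mut, env)
}

#' Selection gradient at a resident trait
#'
#' Partial derivatives of the invasion fitness with respect to the mutant
#' traits, evaluated at mutant = resident. Central finite differences in the
#' interior; one-sided differences within \code{step} of a boundary (the
#' power-law cost is not differentiable at 0).
#'
#' @param x_res,y_res Resident traits.
#' @param env A [dol_env()].
#' @param step Finite-difference step.
#' @return Numeric vector \code{c(gx, gy)} (payoff units per trait unit).
#' @export
selection_gradient <- function(x_res, y_res, env, step = 1e-6) {
  f <- function(xm, ym) invasion_fitness(xm, ym, x_res, y_res, env)
  f0 <- f(x_res, y_res)
  upx <- min(1 - y_res, 1)  # mutant x may not leave the simplex
  gx <- if (x_res > step && x_res < upx - step)
    (f(x_res + step, y_res) - f(x_res - step, y_res)) / (2 * step)
  else if (x_res <= step)
    (f(x_res + step, y_res) - f0) / step
  else (f0 - f(x_res - step, y_res)) / step
  upy <- min(1 - x_res, 1)
  gy <- if (y_res > step && y_res < upy - step)
    (f(x_res, y_res + step) - f(x_res, y_res - step)) / (2 * step)
  else if (y_res <= step)
    (f(x_res, y_res + step) - f0) / step
  else (f0 - f(x_res, y_res - step)) / step
  c(gx = gx, gy = gy)
}

# second derivatives of invasion fitness w.r.t. the mutant traits
mutant_hessian <- function(x_res, y_res, env, step = 1e-4) {
  f <- function(xm, ym) invasion_fitness(xm, ym, x_res, y_res, env)
  # keep the stencil inside the admissible box
  hx <- min(step, x_res / 2, (1 - x_res - y_res) / 2 + step * (x_res + y_res >= 1))
  hx <- max(hx, 1e-6)
  hy <- max(min(step, y_res / 2), 1e-6)
  f0 <- f(x_res, y_res)
  dxx <- (f(min(x_res + hx, 1 - y_res), y_res) - 2 * f0 +
            f(max(x_res - hx, 0), y_res)) / hx^2
  dyy <- (f(x_res, min(y_res + hy, 1 - x_res)) - 2 * f0 +
            f(x_res, max(y_res - hy, 0))) / hy^2
  xp <- min(x_res + hx, 1 - y_res); xm <- max(x_res - hx, 0)
  yp <- min(y_res + hy, 1 - x_res); ym <- max(y_res - hy, 0)
  dxy <- (f(min(xp, 1 - yp), yp) - f(min(xp, 1 - ym), ym) -
            f(xm, yp) + f(xm, ym)) / ((xp - xm) * (yp - ym))
  matrix(c(dxx, dxy, dxy, dyy), 2, 2,
         dimnames = list(c("x", "y"), c("x", "y")))
}

# Jacobian of the selection-gradient field w.r.t. the resident traits
convergence_jacobian <- function(x_res, y_res, env, step = 1e-4) {
  gpx <- selection_gradient(min(x_res + step, 1 - y_res), y_res, env)
  gmx <- selection_gradient(max(x_res - step, 0), y_res, env)
  gpy <- selection_gradient(x_res, min(y_res + step, 1 - x_res), env)
  gmy <- selection_gradient(x_res, max(y_res - step, 0), env)
  J <- cbind((gpx - gmx) / (min(x_res + step, 1 - y_res) - max(x_res - step, 0)),
             (gpy - gmy) / (min(y_res + step, 1 - x_res) - max(y_res - step, 0)))
  dimnames(J) <- list(c("gx", "gy"), c("x", "y"))
  J
}

#' Classify a singular strategy
#'
#' Second-order classification of a resident trait at which the selection
#' gradient (projected onto the feasible directions, for boundary points)
#' vanishes. Interior points are labelled \code{"ESS_stable"} when they are
#' convergence stable (all real parts of the convergence Jacobian negative)
#' and no mutant direction has positive fitness curvature;
#' \code{"branching"} when convergence stable but disruptively curved
#' (largest mutant-Hessian eigenvalue positive); \code{"repeller"} when not
#' convergence stable. Points on the simplex boundary are labelled
#' \code{"boundary"}, with the disruptive curvature taken along the feasible
#' tangent of the active constraint.
#'
#' @param x,y Candidate singular trait pair.
#' @param env A [dol_env()].
#' @param tol Gradient-norm tolerance for accepting the point as singular.
#' @param step Finite-difference step for the second-order terms.
#' @return An object of class \code{dol_singular_point}: list with
#'   \code{x}, \code{y}, \code{z}, \code{gradient_norm},
#'   \code{hessian_eigenvalues}, \code{jacobian_real_parts},
#'   \code{disruptive} (leading feasible curvature) and \code{label}.
#' @export
classify_singular_point <- function(x, y, env, tol = 1e-6, step = 1e-4) {
  g <- selection_gradient(x, y, env)
  gp <- project_gradient(x, y, g)
  if (sqrt(sum(gp^2)) > tol)
    stop("point is not singular: projected gradient norm ",
         format(sqrt(sum(gp^2))), call. = FALSE)
  on_edge <- x + y >= 1 - 1e-9
  at_zero_x <- x <= 1e-9
  at_zero_y <- y <= 1e-9
  H <- mutant_hessian(x, y, env, step)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  J <- convergence_jacobian(x, y, env, step)
  jr <- Re(eigen(J, only.values = TRUE)$values)
  if (on_edge || at_zero_x || at_zero_y) {
    # curvature along the feasible tangent of the active constraint
    tv <- if (on_edge) c(1, -1) / sqrt(2)
          else if (at_zero_x) c(0, 1) else c(1, 0)
    dis <- as.numeric(t(tv) %*% H %*% tv)
    label <- "boundary"
  } else {
    dis <- max(ev)
    conv <- all(jr < 0)
    label <- if (!conv) "repeller"
             else if (dis < 0) "ESS_stable"
             else "branching"
  }
  structure(list(x = x, y = y, z = max(0, 1 - x - y),
                 gradient_norm = sqrt(sum(gp^2)),
                 hessian_eigenvalues = ev, jacobian_real_parts = jr,
                 disruptive = dis, label = label),
            class = "dol_singular_point")
}

#' @export
print.dol_singular_point <- function(x, ...) {
  cat(sprintf("<singular point> (%.4f, %.4f, z = %.4f): %s\n",
              x$x, x$y, x$z, x$label))
  cat(sprintf("  mutant-Hessian eigenvalues: %s; convergence real parts: %s\n",
              paste(signif(x$hessian_eigenvalues, 3), collapse = ", "),
              paste(signif(x$jacobian_real_parts, 3), collapse = ", ")))
  invisible(x)
}

# remove gradient components that point out of the simplex at its boundary
project_gradient <- function(x, y, g) {
  if (x <= 1e-9 && g[1] < 0) g[1] <- 0
  if (y <= 1e-9 && g[2] < 0) g[2] <- 0
  if (x + y >= 1 - 1e-9 && sum(g) > 0) g <- g - sum(g) / 2
  g
}

#' Locate singular strategies by multi-start root finding
#'
#' Minimises the squared selection-gradient norm from \code{n_starts}
#' interior seeds (a fixed low-discrepancy lattice shifted by the RNG),
#' keeps converged interior roots, deduplicates them within
#' \code{dedupe_tol}, and classifies each via
#' [classify_singular_point()].
#'
#' @param env A [dol_env()].
#' @param n_starts Number of starts.
#' @param seed RNG seed for the start jitter.
#' @param tol Gradient-norm acceptance tolerance.
#' @param dedupe_tol Distance below which two roots are considered one.
#' @return List of \code{dol_singular_point} records (possibly empty, with
#'   a \code{"no_convergence"} attribute set when nothing converged).
#' @export
find_singular_points <- function(env, n_starts = 25L, seed = 1L,
                                 tol = 1e-6, dedupe_tol = 1e-6) {
  set.seed(as.integer(seed))
  ns <- max(1L, as.integer(n_starts))
  starts <- cbind(stats::runif(ns, 0.02, 0.95),
                  stats::runif(ns, 0.02, 0.95))
  keep <- starts[, 1] + starts[, 2] < 0.98
  starts <- rbind(starts[keep, , drop = FALSE], c(0.3, 0.6), c(0.2, 0.4))
  # the gradient-flow attractor is itself a prime candidate: its basin
  # under |g|^2 minimisation can be tiny when a repeller sits nearby
  fl <- ad_flow(env)
  if (fl$converged && fl$x > 1e-3 && fl$y > 1e-3 && fl$x + fl$y < 1 - 1e-6)
    starts <- rbind(starts, c(fl$x, fl$y))
  obj <- function(v) {
    # smooth penalty outside the simplex so box-constrained starts survive
    excess <- v[1] + v[2] - 0.999
    if (excess > 0) return(1e3 * (1 + excess)^2)
    sum(selection_gradient(v[1], v[2], env)^2)
  }
  polish <- function(v) {
    # damped Newton on the gradient field to machine-level residuals
    for (it in 1:30) {
      g <- selection_gradient(v[1], v[2], env)
      if (sqrt(sum(g^2)) < tol / 10) break
      J <- convergence_jacobian(v[1], v[2], env)
      dv <- tryCatch(solve(J, -g), error = function(e) NULL)
      if (is.null(dv)) break
      dv <- pmax(pmin(dv, 0.05), -0.05)
      vn <- pmin(pmax(v + dv, 1e-4), 0.999)
      if (vn[1] + vn[2] > 0.999) vn <- vn * 0.999 / (vn[1] + vn[2])
      if (sum(selection_gradient(vn[1], vn[2], env)^2) >= sum(g^2)) break
      v <- vn
    }
    v
  }
  roots <- list()
  for (k in seq_len(nrow(starts))) {
    opt <- tryCatch(
      stats::optim(starts[k, ], obj, method = "L-BFGS-B",
                   lower = c(1e-4, 1e-4), upper = c(0.999, 0.999),
                   control = list(factr = 1e4)),
      error = function(e) NULL)
    if (is.null(opt) || sqrt(opt$value) > 1e-3) next
    v <- polish(opt$par)
    if (sqrt(sum(selection_gradient(v[1], v[2], env)^2)) > tol) next
    if (v[1] + v[2] > 1 - 1e-6) next  # boundary roots handled elsewhere
    dup <- any(vapply(roots, function(r)
      sqrt((r[1] - v[1])^2 + (r[2] - v[2])^2) < max(dedupe_tol, 1e-4),
      logical(1)))
    if (!dup) roots[[length(roots) + 1L]] <- v
  }
  out <- lapply(roots, function(v)
    classify_singular_point(v[1], v[2], env, tol = 10 * tol))
  if (!length(out)) attr(out, "no_convergence") <- TRUE
  out
}

#' Gradient flow of the monomorphic dynamics
#'
#' Integrates the trait-substitution (canonical) flow
#' \eqn{\dot{(x, y)} = g(x, y)} from an initial monomorphic trait by
#' projected explicit Euler steps, stopping when the projected gradient norm
#' falls below \code{tol} or the full-inactivity corner is reached.
#'
#' @param env A [dol_env()].
#' @param x0,y0 Initial trait pair.
#' @param max_steps Iteration cap.
#' @param tol Projected-gradient stopping tolerance.
#' @return List with the endpoint \code{x}, \code{y}, the projected
#'   gradient norm \code{gnorm}, \code{converged}, and \code{path} (matrix
#'   of thinned waypoints).
#' @export
ad_flow <- function(env, x0 = 0.3, y0 = 0.6, max_steps = 2e5, tol = 1e-7) {
  x <- x0; y <- y0
  path <- matrix(NA_real_, 0, 2)
  gn <- Inf
  for (i in seq_len(max_steps)) {
    g <- selection_gradient(max(x, 1e-9), max(y, 1e-9), env)
    g <- project_gradient(x, y, g)
    gn <- sqrt(sum(g^2))
    if (gn < tol) break
    dt <- min(0.02, 0.002 / gn)
    x <- min(max(x + dt * g[1], 0), 1)
    y <- min(max(y + dt * g[2], 0), 1)
    s <- x + y
    if (s > 1) { x <- x / s; y <- y / s }
    if (i %% 500L == 1L) path <- rbind(path, c(x, y))
    if (x < 1e-4 && y < 1e-4) { gn <- 0; break }
  }
  list(x = x, y = y, gnorm = gn, converged = gn < max(tol, 1e-5),
       path = path)
}

#' Regime predicted by adaptive dynamics
#'
#' Integrates the monomorphic gradient flow from the initial trait and maps
#' the endpoint onto the three-regime taxonomy: \code{"fully_specialised"}
#' when the flow collapses to the inactivity corner,
#' \code{"branching"} when it reaches a convergence-stable singular point
#' with positive disruptive curvature in a feasible direction, and
#' \code{"uniform"} when the attractor is (second-order) evolutionarily
#' stable.
#'
#' @param env A [dol_env()].
#' @param x0,y0 Initial monomorphic trait.
#' @return List with \code{label}, the flow endpoint, and (when interior)
#'   the \code{dol_singular_point} record.
#' @export
#' @examples
#' \donttest{
#' ad_regime(dol_env_preset("uniform"))$label
#' }
ad_regime <- function(env, x0 = 0.3, y0 = 0.6) {
  fl <- ad_flow(env, x0, y0)
  if (fl$x < 1e-3 && fl$y < 1e-3)
    return(list(label = "fully_specialised", x = fl$x, y = fl$y,
                point = NULL))
  if (!fl$converged)
    return(list(label = "uniform", x = fl$x, y = fl$y, point = NULL,
                note = "flow did not converge; defaulting to uniform"))
  sp <- classify_singular_point(fl$x, fl$y, env, tol = 1e-4)
  label <- switch(sp$label,
    branching = "branching",
    repeller = "branching",  # flow cannot rest on a repeller; defensive
    ESS_stable = "uniform",
    boundary = if (sp$disruptive > 0) "branching" else "uniform")
  list(label = label, x = fl$x, y = fl$y, point = sp)
}

#' Selection-gradient vector field on the simplex
#'
#' Evaluates the selection gradient on a uniform lattice of the trait
#' simplex, for streamline-style visualisation and export.
#'
#' @param env A [dol_env()].
#' @param resolution Number of lattice points per axis (at least 2).
#' @return Data frame with columns \code{x}, \code{y}, \code{gx},
#'   \code{gy}, \code{fitness} (resident monomorphic payoff).
#' @export
canonical_vector_field <- function(env, resolution = 20L) {
  resolution <- as.integer(resolution)
  if (is.na(resolution) || resolution < 2L)
    stop("'resolution' must be an integer >= 2", call. = FALSE)
  s <- seq(0.01, 0.99, length.out = resolution)
  pts <- expand.grid(x = s, y = s)
  pts <- pts[pts$x + pts$y <= 1, , drop = FALSE]
  g <- t(vapply(seq_len(nrow(pts)),
                function(k) selection_gradient(pts$x[k], pts$y[k], env),
                numeric(2)))
  fit <- vapply(seq_len(nrow(pts)), function(k)
    invasion_fitness(pts$x[k], pts$y[k], pts$x[k], pts$y[k], env),
    numeric(1))
  data.frame(x = pts$x, y = pts$y, gx = g[, 1], gy = g[, 2], fitness = fit,
             row.names = NULL)
}
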