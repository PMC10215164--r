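#' Environment parameters for the division-of-labour game
#'
#' Bundles the shape parameters of the two collective benefit functions and
#' the two individual cost functions, plus the interaction group size
#' \code{n}. Task X has a concave (quadratic) benefit in the group's
#' collective X-effort; task Y has a sigmoidal (thresholding) benefit in the
#' collective Y-effort; inactivity (Z) yields no benefit and costs nothing.
#'
#' The benefit of task X is \eqn{B_X(E) = b_1 E + b_2 E^2}{B_X(E) = b1*E +
#' b2*E^2}, concave for \code{b2 < 0}. The benefit of task Y is the logistic
#' \eqn{B_Y(E) = 1 / (1 + e^{-\beta (E - 1/w)})}{B_Y(E) = 1/(1 +
#' exp(-beta*(E - 1/w)))}, normalised to (0, 1); \code{1/w} is the collective
#' effort at which half the maximal benefit is reached, so it plays the role
#' of the minimum amount of work the task requires. Costs are power laws
#' \eqn{C_X(x) = c_x x^{e_x}} and \eqn{C_Y(y) = c_y y^{e_y}} of the
#' individual effort shares, with exponents in (0, 1] (strictly concave, i.e.
#' marginally decreasing, when below 1).
#'
#' @param b1 Linear benefit coefficient for task X (payoff units per unit
#'   collective effort).
#' @param b2 Quadratic benefit coefficient for task X (payoff units per
#'   squared collective effort; negative for a concave, homeostatic task).
#' @param beta Slope of the task-Y benefit sigmoid (per unit collective
#'   effort).
#' @param w Inflection parameter of the task-Y benefit; \code{1/w} is the
#'   collective effort at the sigmoid midpoint. Must be positive.
#' @param n Group size of the n-player game (integer, at least 2).
#' @param cost_coeff_x,cost_coeff_y Cost scale constants (payoff units),
#'   non-negative.
#' @param cost_exp_x,cost_exp_y Cost exponents in (0, 1].
#'
#' @return An object of class \code{dol_env}: a validated list with the
#'   above fields.
#' @seealso [dol_env_preset()] for the three ready-made environments,
#'   [payoff()] for the resulting game payoff.
#' @export
#' @examples
#' env <- dol_env(b1 = 20, b2 = -4, w = 0.3)
#' benefit_task_x(2.5, dol_env(b1 = 20, b2 = -4, w = 0.3))
dol_env <- function(b1, b2, beta = 3, w, n = 5L,
                    cost_coeff_x = 2.1, cost_coeff_y = 1.5,
                    cost_exp_x = 0.8, cost_exp_y = 0.5) {
  stopifnot(is.numeric(b1), length(b1) == 1L, is.finite(b1),
            is.numeric(b2), length(b2) == 1L, is.finite(b2))
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("'beta' must be a single positive number", call. = FALSE)
  if (!is.numeric(w) || length(w) != 1L || w <= 0)
    stop("'w' must be a single positive number", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 2L)
    stop("'n' (group size) must be an integer >= 2", call. = FALSE)
  for (cc in list(cost_coeff_x = cost_coeff_x, cost_coeff_y = cost_coeff_y)) {
    if (!is.numeric(cc) || length(cc) != 1L || cc < 0 || !is.finite(cc))
      stop("cost coefficients must be single non-negative numbers", call. = FALSE)
  }
  for (ee in list(cost_exp_x = cost_exp_x, cost_exp_y = cost_exp_y)) {
    if (!is.numeric(ee) || length(ee) != 1L || ee <= 0 || ee > 1)
      stop("cost exponents must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(b1 = as.numeric(b1), b2 = as.numeric(b2), beta = as.numeric(beta),
         w = as.numeric(w), n = n,
         cost_coeff_x = as.numeric(cost_coeff_x),
         cost_coeff_y = as.numeric(cost_coeff_y),
         cost_exp_x = as.numeric(cost_exp_x),
         cost_exp_y = as.numeric(cost_exp_y)),
    class = "dol_env")
}

#' @export
print.dol_env <- function(x, ...) {
  cat("<dol_env> n =", x$n, "\n")
  cat(sprintf("  B_X(E) = %g E %+g E^2\n", x$b1, x$b2))
  cat(sprintf("  B_Y(E) = logistic(beta = %g, midpoint 1/w = %g)\n",
              x$beta, 1 / x$w))
  cat(sprintf("  C(x, y) = %g x^%g + %g y^%g\n",
              x$cost_coeff_x, x$cost_exp_x, x$cost_coeff_y, x$cost_exp_y))
  invisible(x)
}

#' Named environment presets
#'
#' Three environments spanning the qualitative regimes of the game:
#' \describe{
#'   \item{\code{"specialised"}}{\code{b1 = 16, b2 = -6, w = 0.2}. The task-Y
#'     threshold (collective effort 5) is unreachable for a group of five, so
#'     benefits never pay for costs and the whole population converges on full
#'     inactivity.}
#'   \item{\code{"branching"}}{\code{b1 = 20, b2 = -4, w = 0.3}. The
#'     population first converges on an interior trait, which is a
#'     convergence-stable singular strategy that is not an ESS: disruptive
#'     selection then splits the population into coexisting trait clusters.}
#'   \item{\code{"uniform"}}{\code{b1 = 28, b2 = -6, w = 0.5}. The interior
#'     singular strategy is a (convergence-stable) ESS with a non-zero
#'     inactivity share; the population settles on it uniformly.}
#' }
#' All other parameters take the package defaults of [dol_env()].
#'
#' @param name One of \code{"specialised"}, \code{"branching"},
#'   \code{"uniform"}.
#' @param ... Overrides passed on to [dol_env()].
#' @return A [dol_env()] object.
#' @export
#' @examples
#' dol_env_preset("branching")
dol_env_preset <- function(name = c("specialised", "branching", "uniform"),
                           ...) {
  name <- match.arg(name)
  base <- switch(name,
    specialised = list(b1 = 16, b2 = -6, w = 0.2),
    branching   = list(b1 = 20, b2 = -4, w = 0.3),
    uniform     = list(b1 = 28, b2 = -6, w = 0.5))
  do.call(dol_env, utils::modifyList(base, list(...)))
}

#' Collective benefit of task X
#'
#' Quadratic benefit \eqn{B_X(E) = b_1 E + b_2 E^2} of the group's summed
#' X-effort. Concave whenever \code{b2 < 0}; zero at zero effort.
#'
#' @param effort_total Collective X-effort, in \eqn{[0, n]}. Vectorised.
#' @param env A [dol_env()].
#' @return Benefit in payoff units.
#' @export
benefit_task_x <- function(effort_total, env) {
  check_effort(effort_total, env)
  env$b1 * effort_total + env$b2 * effort_total^2
}

#' Collective benefit of task Y
#'
#' Logistic (thresholding) benefit
#' \eqn{B_Y(E) = 1/(1 + e^{-\beta(E - 1/w)})} of the group's summed Y-effort,
#' normalised to (0, 1). Strictly increasing; equals 1/2 at \eqn{E = 1/w},
#' where its slope is \eqn{\beta/4}.
#'
#' @inheritParams benefit_task_x
#' @return Benefit in (0, 1).
#' @export
benefit_task_y <- function(effort_total, env) {
  check_effort(effort_total, env)
  stats::plogis(env$beta * (effort_total - 1 / env$w))
}

check_effort <- function(effort_total, env) {
  if (!is.numeric(effort_total) || anyNA(effort_total))
    stop("collective effort must be numeric and non-missing", call. = FALSE)
  if (any(effort_total < 0 | effort_total > env$n))
    stop("collective effort must lie in [0, n]", call. = FALSE)
  invisible(TRUE)
}

#' Shared group benefit
#'
#' Multiplicative coupling of the two task benefits,
#' \eqn{B(X, Y) = \frac{1}{n} B_X(X)\, B_Y(Y)}: both tasks must be staffed
#' for the group to profit, and every member of the group receives the same
#' benefit. Zero whenever the collective X-effort is zero.
#'
#' @param x_total,y_total Collective X- and Y-efforts of the group, each in
#'   \eqn{[0, n]}. Vectorised in parallel.
#' @param env A [dol_env()].
#' @return Per-member benefit in payoff units.
#' @export
group_benefit <- function(x_total, y_total, env) {
  benefit_task_x(x_total, env) * benefit_task_y(y_total, env) / env$n
}

#' Individual cost of task engagement
#'
#' Additive power-law costs \eqn{C(x, y) = c_x x^{e_x} + c_y y^{e_y}} of an
#' agent's own effort shares. Inactivity is free: the cost does not depend on
#' \eqn{z = 1 - x - y}.
#'
#' @param x,y Individual effort shares (vectorised in parallel); each in
#'   \eqn{[0, 1]} with \eqn{x + y \le 1}.
#' @param env A [dol_env()].
#' @return Cost in payoff units (non-negative).
#' @export
individual_cost <- function(x, y, env) {
  check_strategy(x, y)
  env$cost_coeff_x * x^env$cost_exp_x + env$cost_coeff_y * y^env$cost_exp_y
}

#' Payoff of one group member
#'
#' Game payoff of member \code{member} in a group: the shared group benefit
#' minus the member's own cost,
#' \eqn{\Pi = B(X, Y) - C(x_j, y_j)}.
#'
#' @param member Index of the focal member within the group.
#' @param group_x,group_y Effort shares of all group members (numeric vectors
#'   of length \code{env$n}).
#' @param env A [dol_env()].
#' @return Payoff in payoff units.
#' @export
#' @examples
#' env <- dol_env(b1 = 20, b2 = -4, w = 0.5,
#'                cost_coeff_x = 0, cost_coeff_y = 0)
#' payoff(1, rep(0.5, 5), rep(0.4, 5), env)
payoff <- function(member, group_x, group_y, env) {
  if (length(group_x) != env$n || length(group_y) != env$n)
    stop("group must have exactly n = ", env$n, " members", call. = FALSE)
  if (member < 1L || member > env$n)
    stop("'member' must index into the group", call. = FALSE)
  check_strategy(group_x, group_y)
  group_benefit(sum(group_x), sum(group_y), env) -
    individual_cost(group_x[member], group_y[member], env)
}

#' Certified payoff bounds
#'
#' Returns an interval guaranteed to contain every achievable payoff of the
#' game, over all group compositions on the trait simplex. Used by the
#' cross-learning rule, which requires payoffs normalised to \eqn{[0, 1]}.
#'
#' The bound uses the analytic envelope of the benefit: for concave
#' \eqn{B_X} the maximum lies at the vertex \eqn{-b_1/(2 b_2)} (clamped to
#' \eqn{[0, n]}) and the extremes otherwise at the endpoints, while
#' \eqn{B_Y \in (0, 1)} is increasing; the cost maximum over the simplex is
#' found on the hypotenuse \eqn{x + y = 1} (costs increase in both shares).
#'
#' @param env A [dol_env()].
#' @return Named numeric vector \code{c(min = ..., max = ...)} with
#'   \code{min < max}.
#' @export
payoff_bounds <- function(env) {
  ends <- c(0, env$n)
  cand <- ends
  if (env$b2 != 0) {
    vertex <- -env$b1 / (2 * env$b2)
    if (vertex > 0 && vertex < env$n) cand <- c(cand, vertex)
  }
  bx <- env$b1 * cand + env$b2 * cand^2
  by_max <- benefit_task_y(env$n, env)
  # B_Y in (0, by_max]; product extremes depend on the sign of B_X
  ben_max <- max(0, max(bx) * by_max) / env$n
  ben_min <- min(0, min(bx) * by_max) / env$n
  cost_max <- max_cost_on_simplex(env)
  b <- c(min = ben_min - cost_max, max = ben_max)
  if (b["max"] <= b["min"])  # fully degenerate game (all benefits <= 0, no costs)
    b["max"] <- b["min"] + 1e-9
  b
}

# cost is increasing in both shares, so the simplex maximum sits on the
# hypotenuse; the 1-D profile there is concave for exponents < 1
max_cost_on_simplex <- function(env) {
  g <- function(x) env$cost_coeff_x * x^env$cost_exp_x +
    env$cost_coeff_y * (1 - x)^env$cost_exp_y
  opt <- stats::optimize(g, interval = c(0, 1), maximum = TRUE)
  max(opt$objective, g(0), g(1))
}

# shared simplex validation for vectors of effort shares
check_strategy <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    stop("effort shares must be numeric vectors of equal length", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("effort shares must not contain NA", call. = FALSE)
  if (any(x < 0) || any(y < 0))
    stop("effort shares must be non-negative", call. = FALSE)
  if (any(x + y > 1 + 1e-12))
    stop("effort shares must satisfy x + y <= 1", call. = FALSE)
  invisible(TRUE)
}

#' Construct strategies on the trait simplex
#'
#' A strategy is a point \eqn{(x, y, z)} of the unit simplex: effort shares
#' in task X, task Y and inactivity, with \eqn{z = 1 - x - y} implied.
#' Violations of the simplex constraints are errors, never silently
#' repaired.
#'
#' @param x,y Effort shares; vectors of equal length.
#' @return A data frame with columns \code{x}, \code{y}, \code{z}.
#' @export
#' @examples
#' strategy(c(0.3, 0), c(0.6, 0))
strategy <- function(x, y) {
  check_strategy(x, y)
  data.frame(x = as.numeric(x), y = as.numeric(y),
             z = pmax(0, 1 - as.numeric(x) - as.numeric(y)))
}
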