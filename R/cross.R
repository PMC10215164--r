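#' Discretised action space for cross-learning
#'
#' Partitions the trait square into half-open bins of side \code{h} and
#' keeps those whose lower corner lies strictly inside the unit simplex:
#' index pairs \eqn{(i, j)} with \eqn{i, j \ge 0} and
#' \eqn{i + j \le \lceil 1/h \rceil - 1}. Each bin carries the range
#' \eqn{[ih, (i+1)h) \times [jh, (j+1)h)} and its centre
#' \eqn{((i + 1/2) h, (j + 1/2) h)}. At \code{h = 0.05} this yields the 210
#' bins of the fine-grained action space; at \code{h = 0.5} the three corner
#' bins.
#'
#' @param h Bin side length in (0, 1].
#' @return An object of class \code{dol_bin_grid}: list with \code{h},
#'   \code{m} (bin count), \code{bins} (data frame \code{i, j, x_lo, y_lo,
#'   x_hi, y_hi, x_center, y_center} in row-major \code{(i, j)} order) and
#'   \code{lookup} (matrix mapping index pairs to bin numbers, 0 where
#'   outside the simplex).
#' @export
#' @examples
#' build_bin_grid(0.5)$m   # 3
#' build_bin_grid(0.05)$m  # 210
build_bin_grid <- function(h) {
  if (!is.numeric(h) || length(h) != 1L || h <= 0 || h > 1)
    stop("'h' must be a single number in (0, 1]", call. = FALSE)
  mi <- ceiling(1 / h) - 1L  # largest per-axis index
  grid <- expand.grid(j = 0:mi, i = 0:mi)[, c("i", "j")]
  grid <- grid[grid$i + grid$j <= mi, , drop = FALSE]
  grid <- grid[order(grid$i, grid$j), , drop = FALSE]
  rownames(grid) <- NULL
  bins <- data.frame(
    i = grid$i, j = grid$j,
    x_lo = grid$i * h, y_lo = grid$j * h,
    x_hi = (grid$i + 1) * h, y_hi = (grid$j + 1) * h,
    x_center = (grid$i + 0.5) * h, y_center = (grid$j + 0.5) * h)
  lookup <- matrix(0L, mi + 1L, mi + 1L)
  lookup[cbind(bins$i + 1L, bins$j + 1L)] <- seq_len(nrow(bins))
  structure(list(h = h, m = nrow(bins), bins = bins, lookup = lookup),
            class = "dol_bin_grid")
}

#' @export
print.dol_bin_grid <- function(x, ...) {
  cat(sprintf("<dol_bin_grid> h = %g, %d bins\n", x$h, x$m))
  invisible(x)
}

#' Locate the bin containing a trait pair
#'
#' Half-open membership; points whose floor index pair would leave the
#' simplex (the hypotenuse \eqn{x + y = 1}) are assigned the outermost bin
#' still inside it, and traits exactly at 1 fall to the last bin of their
#' axis.
#'
#' @param x,y Trait coordinates (vectorised).
#' @param grid A [build_bin_grid()] grid.
#' @return Integer bin indices.
#' @export
bin_of <- function(x, y, grid) {
  check_strategy(x, y)
  mi <- nrow(grid$lookup) - 1L
  i <- pmin(floor(x / grid$h), mi)
  j <- pmin(floor(y / grid$h), mi)
  j <- pmin(j, mi - i)
  grid$lookup[cbind(i + 1L, j + 1L)]
}

#' Configuration for a cross-learning run
#'
#' Parameters of the modified cross-learning dynamics: each agent holds a
#' probability vector over the bins of a [build_bin_grid()], samples a bin
#' each generation, realizes a trait pair by Gaussian jitter around the bin
#' centre, plays the game, and reinforces the bin its realized traits fell
#' into by the cross rule with its normalised payoff.
#'
#' @param N Population size.
#' @param T Number of generations.
#' @param alpha Learning rate in (0, 1].
#' @param h Bin side length.
#' @param jitter_sigma Standard deviation of the Gaussian realization around
#'   bin centres; defaults to \code{h/4} so that most realizations stay in
#'   the chosen bin.
#' @param x0,y0 Initial trait pair; the initial policy is a point mass on
#'   the bin containing it.
#' @param thin,store_payoffs As in [social_config()].
#' @return An object of class \code{dol_cross_config}.
#' @export
cross_config <- function(N = 200L, T = 10000L, alpha = 0.01, h = 0.05,
                         jitter_sigma = h / 4, x0 = 0.3, y0 = 0.6,
                         thin = 10L, store_payoffs = FALSE) {
  N <- as.integer(N); T <- as.integer(T); thin <- as.integer(thin)
  if (is.na(N) || N < 2L) stop("'N' must be an integer >= 2", call. = FALSE)
  if (is.na(T) || T < 1L) stop("'T' must be an integer >= 1", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("'alpha' must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(h) || h <= 0 || h > 1)
    stop("'h' must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(jitter_sigma) || jitter_sigma < 0)
    stop("'jitter_sigma' must be non-negative", call. = FALSE)
  check_strategy(x0, y0)
  if (is.na(thin) || thin < 1L) stop("'thin' must be >= 1", call. = FALSE)
  structure(list(N = N, T = T, alpha = alpha, h = h,
                 jitter_sigma = jitter_sigma, x0 = x0, y0 = y0, thin = thin,
                 store_payoffs = isTRUE(store_payoffs)),
            class = "dol_cross_config")
}

#' Realize an action from a policy
#'
#' Samples a bin from the policy, draws the trait pair from a Gaussian
#' around its centre (clipped per trait, then simplex-repaired), and
#' reports the bin the realized pair actually falls into — which may differ
#' from the chosen one.
#'
#' @param probs Policy vector over the grid's bins (non-negative, summing
#'   to 1).
#' @param grid A [build_bin_grid()].
#' @param jitter_sigma Gaussian realization spread.
#' @return List with \code{x}, \code{y}, \code{chosen}, \code{realized}.
#' @export
realize_action <- function(probs, grid, jitter_sigma) {
  if (length(probs) != grid$m || any(probs < 0) || sum(probs) <= 0)
    stop("'probs' must be a non-negative vector over the grid's bins",
         call. = FALSE)
  a <- sample.int(grid$m, 1L, prob = probs)
  x <- min(max(stats::rnorm(1, grid$bins$x_center[a], jitter_sigma), 0), 1)
  y <- min(max(stats::rnorm(1, grid$bins$y_center[a], jitter_sigma), 0), 1)
  s <- x + y
  if (s > 1) { x <- x / s; y <- y / s }
  list(x = x, y = y, chosen = a, realized = bin_of(x, y, grid))
}

#' Normalise a payoff to the unit interval
#'
#' Affine map of a raw game payoff onto \eqn{[0, 1]} using certified payoff
#' bounds, clipped at the ends. The cross-learning update is only valid for
#' non-negative reinforcements, which raw payoffs (possibly negative) do not
#' guarantee.
#'
#' @param pi_raw Raw payoff (vectorised).
#' @param bounds Bounds as returned by [payoff_bounds()].
#' @return Values in \eqn{[0, 1]}.
#' @export
normalize_payoff <- function(pi_raw, bounds) {
  rng <- bounds[["max"]] - bounds[["min"]]
  if (!is.finite(rng) || rng <= 0)
    stop("degenerate payoff bounds", call. = FALSE)
  pmin(pmax((pi_raw - bounds[["min"]]) / rng, 0), 1)
}

#' Cross-learning reinforcement update
#'
#' The cross rule: the realized bin \code{realized} gains
#' \eqn{\alpha \hat\Pi (1 - \pi_I)} while every other entry shrinks by the
#' factor \eqn{1 - \alpha \hat\Pi}. The total probability is conserved
#' algebraically and all entries stay in \eqn{[0, 1]}.
#'
#' @param probs Policy vector.
#' @param realized Index of the realized bin.
#' @param pi_hat Normalised payoff in \eqn{[0, 1]}.
#' @param alpha Learning rate in (0, 1].
#' @return Updated policy vector.
#' @export
#' @examples
#' cross_update(c(0.5, 0.5), 1, 1, 0.01)  # c(0.505, 0.495)
cross_update <- function(probs, realized, pi_hat, alpha) {
  if (!is.numeric(pi_hat) || length(pi_hat) != 1L || pi_hat < 0 || pi_hat > 1)
    stop("'pi_hat' must be a single value in [0, 1]", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("'alpha' must lie in (0, 1]", call. = FALSE)
  if (realized < 1L || realized > length(probs))
    stop("'realized' must index into the policy", call. = FALSE)
  out <- probs * (1 - alpha * pi_hat)
  out[realized] <- out[realized] + alpha * pi_hat
  out
}

#' Run the individual-learning (cross-learning) dynamics
#'
#' Iterates, per generation: action realization for every agent, random
#' partition into games, payoff evaluation, payoff normalisation by the
#' environment's certified bounds, and the cross update of every agent's
#' policy on its realized bin. Stores realized trait profiles and the
#' policy-expected trait of every agent at each stored generation, plus the
#' final policy matrix.
#'
#' @param config A [cross_config()].
#' @param env A [dol_env()].
#' @param seed Integer RNG seed.
#' @return A \code{dol_trajectory} with additional fields
#'   \code{expected_x}, \code{expected_y}, \code{chosen_bin},
#'   \code{realized_bin}, \code{policy} and \code{grid}.
#' @export
#' @examples
#' traj <- run_individual(cross_config(N = 20, T = 50),
#'                        dol_env_preset("uniform"), seed = 1)
#' tail(mean_trait_trajectory(traj), 2)
run_individual <- function(config, env, seed = 1L) {
  stopifnot(inherits(config, "dol_cross_config"), inherits(env, "dol_env"))
  if (config$N %% env$n != 0L)
    stop("population size N must be divisible by the group size n",
         call. = FALSE)
  grid <- build_bin_grid(config$h)
  b0 <- bin_of(config$x0, config$y0, grid)
  bounds <- payoff_bounds(env)
  set.seed(as.integer(seed))
  raw <- sim_cross_cpp(unclass(env), config$N, config$T, config$alpha,
                       config$h, config$jitter_sigma, b0,
                       grid$bins$x_center, grid$bins$y_center, grid$lookup,
                       bounds[["min"]], bounds[["max"]], config$thin,
                       config$store_payoffs)
  structure(list(kind = "individual", x = raw$x, y = raw$y,
                 expected_x = raw$expected_x, expected_y = raw$expected_y,
                 chosen_bin = raw$chosen_bin, realized_bin = raw$realized_bin,
                 modal_bin = raw$modal_bin,
                 policy = raw$policy, grid = grid,
                 generation = as.integer(raw$generation),
                 payoff = if (config$store_payoffs) raw$payoff else NULL,
                 config = config, env = env, seed = as.integer(seed)),
            class = "dol_trajectory")
}
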