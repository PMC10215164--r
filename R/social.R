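#' Configuration for a social-learning run
#'
#' Parameters of the payoff-biased imitation dynamics: each generation the
#' population is partitioned into random n-player games, every agent receives
#' its game payoff, then every agent simultaneously copies the trait pair of
#' a role model drawn from the whole population with Boltzmann probability
#' \eqn{e^{\zeta \Pi_l} / \sum_m e^{\zeta \Pi_m}}, and finally each agent
#' explores with probability \code{mu} by perturbing both traits with
#' Gaussian noise of standard deviation \code{sigma} (clipped to the trait
#' box and rescaled onto the simplex if needed).
#'
#' @param N Population size; must be divisible by the group size of the
#'   environment it is run in.
#' @param T Number of generations (at least 1).
#' @param zeta Selection intensity of the imitation softmax (dimensionless).
#' @param mu Exploration (mutation) probability per agent per generation.
#' @param sigma Standard deviation of the Gaussian trait perturbation.
#' @param x0,y0 Initial monomorphic trait values.
#' @param thin Store every \code{thin}-th generation (the final generation is
#'   always stored).
#' @param store_payoffs Keep the per-agent payoff at stored generations.
#' @return An object of class \code{dol_social_config}.
#' @export
social_config <- function(N = 200L, T = 10000L, zeta = 2, mu = 0.01,
                          sigma = 0.005, x0 = 0.3, y0 = 0.6, thin = 10L,
                          store_payoffs = FALSE) {
  N <- as.integer(N); T <- as.integer(T); thin <- as.integer(thin)
  if (is.na(N) || N < 2L) stop("'N' must be an integer >= 2", call. = FALSE)
  if (is.na(T) || T < 1L) stop("'T' must be an integer >= 1", call. = FALSE)
  if (!is.numeric(zeta) || length(zeta) != 1L || !is.finite(zeta))
    stop("'zeta' must be a finite number", call. = FALSE)
  if (!is.numeric(mu) || mu < 0 || mu > 1)
    stop("'mu' must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(sigma) || sigma < 0)
    stop("'sigma' must be non-negative", call. = FALSE)
  check_strategy(x0, y0)
  if (is.na(thin) || thin < 1L) stop("'thin' must be >= 1", call. = FALSE)
  structure(list(N = N, T = T, zeta = zeta, mu = mu, sigma = sigma,
                 x0 = x0, y0 = y0, thin = thin,
                 store_payoffs = isTRUE(store_payoffs)),
            class = "dol_social_config")
}

#' Random partition of the population into games
#'
#' Uniformly random partition of \code{1:N} into \code{K = N/n} disjoint
#' groups of \code{n} (shuffle, then chunk).
#'
#' @param N Population size.
#' @param n Group size; must divide \code{N}.
#' @return A list of \code{K} integer vectors.
#' @export
#' @examples
#' set.seed(1)
#' partition_population(10, 5)
partition_population <- function(N, n) {
  N <- as.integer(N); n <- as.integer(n)
  if (N %% n != 0L)
    stop("'N' must be divisible by the group size 'n'", call. = FALSE)
  split(sample.int(N), rep(seq_len(N %/% n), each = n))
}

#' Payoffs of a population profile under a partition
#'
#' Evaluates every agent's game payoff given a partition into n-player
#' games: the shared benefit of its group's collective efforts minus its own
#' cost.
#'
#' @param x,y Trait vectors of length N.
#' @param partition A partition as returned by [partition_population()].
#' @param env A [dol_env()].
#' @return Numeric payoff vector of length N.
#' @export
compute_payoffs <- function(x, y, partition, env) {
  check_strategy(x, y)
  N <- length(x)
  if (!setequal(unlist(partition), seq_len(N)))
    stop("partition must cover the profile exactly", call. = FALSE)
  pay <- numeric(N)
  for (g in partition) {
    b <- group_benefit(sum(x[g]), sum(y[g]), env)
    pay[g] <- b - individual_cost(x[g], y[g], env)
  }
  pay
}

#' Boltzmann imitation probabilities
#'
#' Probability that each agent is chosen as a role model,
#' \eqn{p_l = e^{\zeta \Pi_l} / \sum_m e^{\zeta \Pi_m}}, computed with a
#' max-shift so that large payoffs cannot overflow.
#'
#' @param payoffs Numeric vector of payoffs.
#' @param zeta Selection intensity.
#' @return Probability vector of the same length, summing to one.
#' @export
#' @examples
#' imitation_probabilities(c(0, log(2) / 2), zeta = 2)  # 1/3, 2/3
imitation_probabilities <- function(payoffs, zeta) {
  if (!all(is.finite(payoffs))) stop("payoffs must be finite", call. = FALSE)
  w <- exp(zeta * (payoffs - max(payoffs)))
  w / sum(w)
}

#' Gaussian trait exploration
#'
#' With probability \code{mu}, perturbs both traits of a strategy with
#' independent Gaussian noise of standard deviation \code{sigma}, clips each
#' trait to \eqn{[0, 1]} and, if the clipped pair leaves the simplex,
#' rescales it onto the boundary \eqn{x + y = 1}.
#'
#' @param x,y Trait pair (single values).
#' @param mu Perturbation probability.
#' @param sigma Perturbation standard deviation.
#' @return Named numeric vector \code{c(x = , y = )}.
#' @export
mutate_strategy <- function(x, y, mu, sigma) {
  check_strategy(x, y)
  if (stats::runif(1) < mu) {
    x <- min(max(stats::rnorm(1, x, sigma), 0), 1)
    y <- min(max(stats::rnorm(1, y, sigma), 0), 1)
    s <- x + y
    if (s > 1) { x <- x / s; y <- y / s }
  }
  c(x = x, y = y)
}

#' Run the social-learning (imitation) dynamics
#'
#' Iterates, for \code{config$T} generations: random partition into games,
#' payoff evaluation, simultaneous population-wide Boltzmann imitation of the
#' previous generation (self-imitation allowed), and Gaussian exploration.
#' The trajectory is fully reproducible from \code{seed}.
#'
#' @param config A [social_config()].
#' @param env A [dol_env()].
#' @param seed Integer RNG seed.
#' @return A \code{dol_trajectory} object; see [as.data.frame.dol_trajectory()].
#' @export
#' @examples
#' traj <- run_social(social_config(N = 20, T = 50), dol_env_preset("uniform"),
#'                    seed = 1)
#' tail(mean_trait_trajectory(traj), 3)
run_social <- function(config, env, seed = 1L) {
  stopifnot(inherits(config, "dol_social_config"), inherits(env, "dol_env"))
  if (config$N %% env$n != 0L)
    stop("population size N must be divisible by the group size n",
         call. = FALSE)
  set.seed(as.integer(seed))
  raw <- sim_social_cpp(unclass(env), config$N, config$T, config$zeta,
                        config$mu, config$sigma, config$x0, config$y0,
                        config$thin, config$store_payoffs)
  structure(list(kind = "social", x = raw$x, y = raw$y,
                 generation = as.integer(raw$generation),
                 payoff = if (config$store_payoffs) raw$payoff else NULL,
                 config = config, env = env, seed = as.integer(seed)),
            class = "dol_trajectory")
}

#' @export
print.dol_trajectory <- function(x, ...) {
  cat(sprintf("<dol_trajectory> %s learning, N = %d, T = %d (%d snapshots), seed %d\n",
              x$kind, ncol(x$x), x$config$T, nrow(x$x), x$seed))
  mt <- utils::tail(mean_trait_trajectory(x), 1)
  cat(sprintf("  final mean traits: x = %.3f, y = %.3f, z = %.3f\n",
              mt$x, mt$y, mt$z))
  invisible(x)
}

#' Trajectory as a long data frame
#'
#' @param x A \code{dol_trajectory}.
#' @param row.names,optional Ignored (standard generic arguments).
#' @param ... Ignored.
#' @return Data frame with columns \code{t}, \code{agent}, \code{x},
#'   \code{y}, \code{z}, plus \code{payoff} when stored and, for
#'   individual-learning runs, \code{chosen_bin} and \code{realized_bin}.
#' @export
as.data.frame.dol_trajectory <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  S <- nrow(x$x); N <- ncol(x$x)
  out <- data.frame(
    t = rep(x$generation, times = N),
    agent = rep(seq_len(N), each = S),
    x = as.vector(x$x),
    y = as.vector(x$y))
  out$z <- pmax(0, 1 - out$x - out$y)
  if (!is.null(x$payoff)) out$payoff <- as.vector(x$payoff)
  if (identical(x$kind, "individual")) {
    out$chosen_bin <- as.vector(x$chosen_bin)
    out$realized_bin <- as.vector(x$realized_bin)
  }
  out[order(out$t, out$agent), , drop = FALSE]
}
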