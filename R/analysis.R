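#' Mean-trait time series of a trajectory
#'
#' Arithmetic mean of \code{x}, \code{y} and \code{z} over agents at every
#' stored generation. Each mean triple lies in the simplex.
#'
#' @param traj A \code{dol_trajectory}.
#' @return Data frame with columns \code{t}, \code{x}, \code{y}, \code{z}.
#' @export
mean_trait_trajectory <- function(traj) {
  stopifnot(inherits(traj, "dol_trajectory"))
  if (!nrow(traj$x)) stop("empty trajectory", call. = FALSE)
  mx <- rowMeans(traj$x); my <- rowMeans(traj$y)
  data.frame(t = traj$generation, x = mx, y = my,
             z = pmax(0, 1 - mx - my))
}

#' Mean inactivity of a population profile
#'
#' @param x,y Trait vectors of a single profile.
#' @return Mean \eqn{z = 1 - x - y} over agents, in \eqn{[0, 1]}.
#' @export
inactivity_level <- function(x, y) {
  check_strategy(x, y)
  mean(pmax(0, 1 - x - y))
}

#' Detect coexisting trait clusters in a profile
#'
#' Runs k-means on the \code{(x, y)} profile for \eqn{k \in \{1, 2, 3\}} and
#' reports the largest \eqn{k} for which every cluster holds at least
#' \code{min_frac} of the agents and all pairwise centroid distances are at
#' least \code{min_sep}. This operationalises the splitting of a population
#' into co-existing traits.
#'
#' @param x,y Trait vectors of a single profile.
#' @param min_frac Minimum fraction of agents per cluster.
#' @param min_sep Minimum Euclidean centroid separation (trait units).
#' @param min_ratio Minimum ratio of each pairwise centroid distance to the
#'   summed RMS radii of the two clusters. This demands an actual
#'   low-density gap between clusters: a broad unimodal cloud can always be
#'   cut in two by k-means, but the halves then sit closer than their own
#'   spread and are rejected.
#' @return List with \code{k}, \code{centers} (k x 2), \code{sizes} and
#'   \code{separation} (minimum pairwise centroid distance; \code{Inf} for
#'   \code{k = 1}).
#' @export
#' @examples
#' set.seed(1)
#' detect_clusters(c(rnorm(50, .8, .01), rnorm(50, .1, .01)),
#'                 c(rnorm(50, .1, .01), rnorm(50, .8, .01)))$k
detect_clusters <- function(x, y, min_frac = 0.15, min_sep = 0.1,
                            min_ratio = 2) {
  check_strategy(x, y)
  pts <- cbind(x, y)
  n_pts <- nrow(unique(pts))
  best <- list(k = 1L, centers = matrix(colMeans(pts), 1, 2),
               sizes = nrow(pts), separation = Inf)
  for (k in 2:3) {
    if (n_pts < k) next
    # with exactly k distinct points, seed kmeans on them directly
    centers <- if (n_pts == k) unique(pts) else k
    km <- tryCatch(
      if (is.matrix(centers))
        stats::kmeans(pts, centers = centers, iter.max = 50L)
      else stats::kmeans(pts, centers = k, nstart = 5L, iter.max = 50L),
      error = function(e) NULL)
    if (is.null(km)) next
    if (!all(km$size >= min_frac * nrow(pts))) next
    radii <- sqrt(km$withinss / km$size)
    ok <- TRUE
    dmin <- Inf
    for (a in seq_len(k - 1)) for (b in seq.int(a + 1, k)) {
      d <- sqrt(sum((km$centers[a, ] - km$centers[b, ])^2))
      dmin <- min(dmin, d)
      if (d < min_sep || d < min_ratio * (radii[a] + radii[b])) ok <- FALSE
    }
    if (ok)
      best <- list(k = k, centers = km$centers, sizes = km$size,
                   separation = dmin)
  }
  best
}

# Trait matrices used for classification. For cross-learning runs the
# committed behavioural type of an agent is its modal action bin (the
# policy's argmax): single-generation realizations carry jitter noise and
# policy-expected traits carry residual exploration mass, both of which
# would blur genuine trait differentiation. Social runs classify on the
# traits themselves.
classification_traits <- function(traj) {
  if (identical(traj$kind, "individual") && !is.null(traj$modal_bin)) {
    cen_x <- traj$grid$bins$x_center
    cen_y <- traj$grid$bins$y_center
    mb <- traj$modal_bin
    list(x = matrix(cen_x[mb], nrow(mb), ncol(mb)),
         y = matrix(cen_y[mb], nrow(mb), ncol(mb)))
  } else list(x = traj$x, y = traj$y)
}

#' Classify the regime of a trajectory
#'
#' Maps a finished run onto the three-regime taxonomy using its tail window
#' (the final \code{tail_frac} of stored generations):
#' \itemize{
#'   \item \code{"fully_specialised"} — tail-window mean inactivity
#'     \eqn{\bar z \ge} \code{z_cut}: the whole population has withdrawn
#'     into the cost-free pseudo-task.
#'   \item \code{"branching"} — [detect_clusters()] finds two or more
#'     coexisting clusters in at least \code{persistence} of the tail
#'     snapshots.
#'   \item \code{"uniform"} — otherwise: a single shared trait combination.
#' }
#' For individual-learning runs the clustering and inactivity are evaluated
#' on the agents' modal action bins (each policy's argmax centre), which are
#' their committed behavioural types; single-generation realizations carry
#' Gaussian jitter, and policy-expected traits carry residual exploration
#' mass, neither of which is trait differentiation.
#'
#' @param traj A \code{dol_trajectory}.
#' @param z_cut Inactivity threshold for the fully specialised label.
#' @param tail_frac Fraction of stored generations forming the tail window.
#' @param persistence Fraction of tail snapshots that must show clusters.
#' @param min_frac,min_sep Passed to [detect_clusters()].
#' @return An object of class \code{dol_regime}: list with \code{label} and
#'   a \code{diagnostics} record (tail mean traits, cluster votes, cluster
#'   summary of the final snapshot, thresholds used).
#' @export
classify_regime <- function(traj, z_cut = 0.9, tail_frac = 0.1,
                            persistence = 0.8, min_frac = 0.15,
                            min_sep = 0.1) {
  stopifnot(inherits(traj, "dol_trajectory"))
  S <- nrow(traj$x)
  if (!S) stop("empty trajectory", call. = FALSE)
  n_tail <- max(1L, ceiling(tail_frac * S))
  rows <- seq.int(S - n_tail + 1L, S)
  tr <- classification_traits(traj)
  zbar <- mean(pmax(0, 1 - tr$x[rows, , drop = FALSE] -
                      tr$y[rows, , drop = FALSE]))
  votes <- vapply(rows, function(r)
    detect_clusters(tr$x[r, ], tr$y[r, ], min_frac, min_sep)$k >= 2L,
    logical(1))
  final <- detect_clusters(tr$x[S, ], tr$y[S, ], min_frac, min_sep)
  label <- if (zbar >= z_cut) "fully_specialised"
           else if (mean(votes) >= persistence) "branching"
           else "uniform"
  structure(list(
    label = label,
    diagnostics = list(
      tail_mean_z = zbar,
      tail_mean_x = mean(tr$x[rows, ]), tail_mean_y = mean(tr$y[rows, ]),
      cluster_vote_fraction = mean(votes),
      final_clusters = final,
      thresholds = list(z_cut = z_cut, tail_frac = tail_frac,
                        persistence = persistence, min_frac = min_frac,
                        min_sep = min_sep),
      tail_generations = traj$generation[rows])),
    class = "dol_regime")
}

#' @export
print.dol_regime <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<regime> %s (tail mean z = %.3f, cluster votes %.0f%%, k = %d)\n",
              x$label, d$tail_mean_z, 100 * d$cluster_vote_fraction,
              d$final_clusters$k))
  invisible(x)
}
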