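#' Load an experiment specification from a YAML file
#'
#' The file may contain the keys \code{environment} (a preset name or a
#' mapping of [dol_env()] arguments: \code{b1, b2, beta, w, n,
#' cost_coeff_x, cost_coeff_y, cost_exp_x, cost_exp_y}), \code{mode} (one
#' of \code{"social"}, \code{"individual"}, \code{"both"}, \code{"field"}),
#' \code{seeds} (distinct integers), \code{social} and \code{individual}
#' (run-parameter mappings forwarded to [social_config()] /
#' [cross_config()]) and \code{out_dir}. Unknown keys at any level are an
#' error, so typos cannot silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return An object of class \code{dol_experiment_spec} with all defaults
#'   resolved.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  known <- c("environment", "mode", "seeds", "social", "individual",
             "out_dir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  env <- resolve_environment(raw$environment)
  mode <- raw$mode %||% "both"
  if (!mode %in% c("social", "individual", "both", "field"))
    stop("'mode' must be one of social, individual, both, field",
         call. = FALSE)
  seeds <- as.integer(raw$seeds %||% 1L)
  if (anyNA(seeds) || anyDuplicated(seeds))
    stop("'seeds' must be distinct integers", call. = FALSE)
  soc <- build_from_list(raw$social, social_config, "social")
  ind <- build_from_list(raw$individual, cross_config, "individual")
  structure(list(env = env, mode = mode, seeds = seeds,
                 social = soc, individual = ind,
                 out_dir = raw$out_dir %||% NULL),
            class = "dol_experiment_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_environment <- function(spec) {
  if (is.null(spec)) stop("config must name an 'environment'", call. = FALSE)
  if (is.character(spec) && length(spec) == 1L)
    return(dol_env_preset(spec))
  if (!is.list(spec))
    stop("'environment' must be a preset name or a mapping", call. = FALSE)
  # YAML 1.1 reads a bare n key as a boolean; undo that
  names(spec)[names(spec) == "FALSE"] <- "n"
  known <- names(formals(dol_env))
  if (!is.null(spec$preset)) {
    preset <- spec$preset
    spec$preset <- NULL
    unknown <- setdiff(names(spec), known)
    if (length(unknown))
      stop("unknown environment key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    return(do.call(dol_env_preset, c(list(name = preset), spec)))
  }
  unknown <- setdiff(names(spec), known)
  if (length(unknown))
    stop("unknown environment key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(dol_env, spec)
}

build_from_list <- function(lst, constructor, what) {
  lst <- lst %||% list()
  # YAML 1.1 reads bare N / T keys as booleans; undo that
  names(lst)[names(lst) == "FALSE"] <- "N"
  names(lst)[names(lst) == "TRUE"] <- "T"
  unknown <- setdiff(names(lst), names(formals(constructor)))
  if (length(unknown))
    stop("unknown ", what, " key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(constructor, lst)
}

#' Write a trajectory to CSV
#'
#' Long format, one row per stored generation and agent, with the resolved
#' run configuration embedded as \code{#}-prefixed JSON header lines so a
#' stored run is self-describing.
#'
#' @param traj A \code{dol_trajectory}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  header <- sprintf(
    "# dolgame trajectory kind=%s seed=%d", traj$kind, traj$seed)
  cfg <- jsonlite::toJSON(
    list(config = unclass(traj$config), env = unclass(traj$env)),
    auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, paste0("# ", cfg)), con)
  utils::write.csv(as.data.frame(traj), con, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path File path.
#' @return Data frame of the trajectory rows, with the embedded
#'   configuration in \code{attr(, "run_info")}.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  info <- NULL
  if (length(hdr) >= 2L)
    info <- jsonlite::fromJSON(sub("^# ", "", lines[hdr[2L]]))
  df <- utils::read.csv(text = lines[setdiff(seq_along(lines), hdr)])
  attr(df, "run_info") <- info
  df
}

#' Run a full comparison experiment
#'
#' For mode \code{"both"}: runs the social-learning and the
#' individual-learning dynamics for every seed, computes the
#' adaptive-dynamics prediction once, classifies every run, and reports
#' whether the three regime labels agree. Modes \code{"social"} and
#' \code{"individual"} run one paradigm only; mode \code{"field"} exports
#' the selection-gradient lattice.
#'
#' @param spec A \code{dol_experiment_spec} from [load_config()], or built
#'   in code.
#' @param out_dir Output directory; when not \code{NULL}, trajectories and a
#'   JSON summary are written there. An existing non-empty directory is
#'   refused unless \code{force}.
#' @param force Overwrite an existing output directory.
#' @param verbose Print per-run progress lines.
#' @return List with the AD prediction, per-seed regime labels per paradigm,
#'   majority labels, and the agreement verdict.
#' @export
run_experiment <- function(spec, out_dir = spec$out_dir, force = FALSE,
                           verbose = FALSE) {
  stopifnot(inherits(spec, "dol_experiment_spec"))
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
      stop("output directory exists and is not empty; use force = TRUE",
           call. = FALSE)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  if (spec$mode == "field") {
    fld <- canonical_vector_field(spec$env)
    if (!is.null(out_dir))
      utils::write.csv(fld, file.path(out_dir, "field.csv"),
                       row.names = FALSE)
    return(list(mode = "field", field = fld))
  }
  ad <- ad_regime(spec$env, spec$social$x0, spec$social$y0)
  res <- list(mode = spec$mode, ad = ad, social = NULL, individual = NULL)
  run_one <- function(kind) {
    labs <- character(0)
    for (s in spec$seeds) {
      traj <- if (kind == "social") run_social(spec$social, spec$env, s)
              else run_individual(spec$individual, spec$env, s)
      reg <- classify_regime(traj)
      labs[as.character(s)] <- reg$label
      if (verbose)
        message(sprintf("%s seed %d: %s (tail z = %.3f)", kind, s,
                        reg$label, reg$diagnostics$tail_mean_z))
      if (!is.null(out_dir))
        write_trajectory(traj, file.path(
          out_dir, sprintf("%s_seed%d.csv", kind, s)))
    }
    labs
  }
  if (spec$mode %in% c("social", "both"))
    res$social <- run_one("social")
  if (spec$mode %in% c("individual", "both"))
    res$individual <- run_one("individual")
  majority <- function(labs) {
    if (is.null(labs)) return(NULL)
    names(sort(table(labs), decreasing = TRUE))[1L]
  }
  res$majority <- list(ad = ad$label,
                       social = majority(res$social),
                       individual = majority(res$individual))
  present <- unlist(res$majority[!vapply(res$majority, is.null, logical(1))])
  res$agreement <- length(unique(present)) == 1L
  if (!is.null(out_dir)) {
    summ <- res
    summ$ad <- list(label = ad$label, x = ad$x, y = ad$y)
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  res
}
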