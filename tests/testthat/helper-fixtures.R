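# Minimal hand-built trajectory objects for classifier tests: a list of
# per-generation (x, y) profiles becomes a dol_trajectory with the social
# layout (snapshot matrices, generations 0-based).
make_trajectory <- function(profiles, kind = "social") {
  S <- length(profiles)
  N <- length(profiles[[1]]$x)
  X <- t(vapply(profiles, function(p) p$x, numeric(N)))
  Y <- t(vapply(profiles, function(p) p$y, numeric(N)))
  structure(list(kind = kind, x = X, y = Y,
                 generation = seq_len(S) - 1L,
                 payoff = NULL, config = NULL, env = NULL, seed = NA_integer_),
            class = "dol_trajectory")
}

# repeat one profile over S generations
constant_trajectory <- function(x, y, S = 20L) {
  make_trajectory(rep(list(list(x = x, y = y)), S))
}

test_env <- function(...) dol_env_preset("branching", ...)
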