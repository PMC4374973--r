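# Shared fixtures: trained networks are expensive, so they are built once
# per test run and cached in this environment.  Small-scale settings keep
# the suite within a normal test budget; scientific conclusions at full
# scale are exercised by scripts/acceptance.R.

.xt_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .xt_cache)) assign(key, expr, envir = .xt_cache)
  get(key, envir = .xt_cache)
}

# a quickly developed control network (full curriculum, early stop)
dev_control <- function(seed = 7) {
  cached(paste0("dev_control_", seed),
         run_development(kappa = 1, seed = seed,
                         config = curriculum_config()))
}

# a tiny configuration for cheap structural tests
tiny_config <- function(...) {
  xt_config(n_hidden = 12, n_pfc = 10, k_hidden = 4, k_pfc = 2, ...)
}
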