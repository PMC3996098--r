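# Shared cache of protocol runs: the transient scenarios are reused by many
# test files, so they are computed once per session on first use.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) assign(key, force(expr), envir = .run_cache)
  get(key, envir = .run_cache)
}

# lesion + matched healthy baseline, recovery horizon 5 min (the clinical
# measurement window), default configuration
pair_300 <- function(stage, depth_mm) {
  cached(sprintf("pair_%s_%g", stage, depth_mm),
         run_scenario(stage, depth_mm, protocol_config(t_end = 300)))
}

# delta at the sub-lesion point P at recovery times t (seconds)
delta_at_P <- function(pair, t) {
  d <- delta_series(pair$dti, pair$healthy, at = "P")
  d$delta_C[match(t, d$t_s)]
}

apex_index <- function(mesh) (length(mesh$skin_nodes) + 1) %/% 2
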