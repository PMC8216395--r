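# Reference simulations shared across acceptance tests (computed once per
# test session). Wild-type runs use the full reference configuration; the
# knockout comparison runs at the 48 h horizon.
.run_cache <- new.env(parent = emptyenv())

# Reference problem size: 140 epithelial founders (the full in-vivo-like
# section uses ~200; the reduced size keeps three 72 h replicates inside
# the suite's runtime while preserving the fragmentation regime).
reference_runs <- function(seeds = 101:103, n_epithelial = 140) {
  key <- paste0("wt_", paste(seeds, collapse = "_"))
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- lapply(seeds, function(s) {
      suppressWarnings(simulate_tissue(
        run_config(duration = 72, seed = s, n_epithelial = n_epithelial)))
    })
  }
  .run_cache[[key]]
}

knockout_runs <- function(seeds = 101:103, duration = 72, n_epithelial = 140) {
  key <- paste0("ko_", paste(seeds, collapse = "_"))
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- lapply(seeds, function(s) {
      suppressWarnings(simulate_tissue(
        run_config(duration = duration, seed = s, vegfa_ko = TRUE,
                   n_epithelial = n_epithelial)))
    })
  }
  .run_cache[[key]]
}

stat_at <- function(run, t, col) {
  s <- run$stats
  s[[col]][which.min(abs(s$time - t))]
}
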