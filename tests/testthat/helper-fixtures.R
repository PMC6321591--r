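# Shared fixtures.  The demo pipeline runs are cached so that the
# determinism, topology and basin-recovery tests share the same two runs.

.fixture_cache <- new.env(parent = emptyenv())

demo_run <- function(which = "a", seed = 1) {
  key <- paste0("demo_", which, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("pmfpath_demo_", which, "_", seed))
    bundle <- suppressMessages(
      run_pipeline(step1_demo_config(seed = seed), outdir = dir))
    .fixture_cache[[key]] <- list(bundle = bundle, dir = dir)
  }
  .fixture_cache[[key]]
}

# small harmonic-recovery umbrella dataset (1D), cached
harmonic_recovery_series <- function(n_prod = 60000, master_seed = 11) {
  key <- paste0("harm_", n_prod, "_", master_seed)
  if (is.null(.fixture_cache[[key]])) {
    sp <- landscape_spec("harmonic", params = list(stiffness = 10),
                         domain = rbind(-2, 2))
    wins <- build_window_grid(c(-1, 1), 0.1, n_equil = 4000,
                              n_prod = n_prod, master_seed = master_seed)
    series <- lapply(wins, function(w) sample_window(sp, w, stride = 10))
    .fixture_cache[[key]] <- list(spec = sp, windows = wins,
                                  series = series)
  }
  .fixture_cache[[key]]
}
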