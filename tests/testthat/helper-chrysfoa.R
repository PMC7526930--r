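# Shared fixtures, computed once per test run.

fixture_records <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_database()
    cache
  }
})

fixture_resolved <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- resolve_records(fixture_records())
    cache
  }
})

fixture_encoded <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- encode_features(fixture_resolved())
    cache
  }
})

# A small, quick synthetic dataset + fitted ensemble for structural tests.
quick_member_configs <- function(seed = 1L) {
  list(mlp = mlp_config(epochs = 60L, seed = seed),
       rbf = rbf_config(seed = seed),
       anfis = anfis_config(epochs = 10L, seed = seed))
}

quick_synth_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n = 200L, seed = 11L)
      gen <- generate_synthetic(cfg)
      enc <- encode_features(gen$rows)
      sp <- split_dataset(enc, seed = 11L)
      ens <- fit_bagged_ensemble(enc$features[sp$training, ],
                                 enc$targets[sp$training],
                                 member_configs = quick_member_configs(),
                                 B = 3L, seed = 11L)
      cache <<- list(cfg = cfg, gen = gen, enc = enc, split = sp, ens = ens)
    }
    cache
  }
})
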