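# Shared reference score distribution for the relative-score tests:
# built once per test run (100 triangle replicates at n_obs = 10,000,
# d = 5, k = 50, 200 trees) and cached.
.ref_cache <- new.env(parent = emptyenv())

shared_reference_table <- function() {
  if (is.null(.ref_cache$table)) {
    .ref_cache$table <- build_reference_table(
      data.frame(n_obs = 10000, d = 5, k = 50), n_reps = 100,
      config = treetop_config(k = 50, n_trees = 200), seed = 1000)
  }
  .ref_cache$table
}

# a hand-built reference distribution for unit tests that exercise
# recursion logic without paying for a calibrated reference
stub_reference_table <- function(b_ref, n_obs = 10000, d = 5, k = 50) {
  structure(list(structure(list(params = list(n_obs = n_obs, d = d, k = k,
                                              rho = 0),
                                max_scores = rep(b_ref, 20), b_ref = b_ref,
                                n_reps = 20),
                           class = "reference_distribution")),
            class = "reference_table")
}
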