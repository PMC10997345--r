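# Memoised study-scale recovery runs shared across test files, so the
# expensive replicate sets are simulated and fitted only once per session.

.recovery_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.recovery_cache[[key]]))
    .recovery_cache[[key]] <- force(expr)
  .recovery_cache[[key]]
}

# 100 replicates at the study's largest day count (N = 36, sigma2 = 0.02).
recovery_records_n36 <- function() {
  memo("n36", run_replicates(example_spec(2), data.frame(N = 36),
                             n_reps = 100, seed = 20260921))
}

# 40 replicates at N = 20, used for the plateau comparison.
recovery_records_n20 <- function() {
  memo("n20", run_replicates(example_spec(2), data.frame(N = 20),
                             n_reps = 40, seed = 424))
}

network_params <- function(k = 2) {
  nm <- ranef_names(k)
  nm[!grepl("^c_", nm)]
}
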