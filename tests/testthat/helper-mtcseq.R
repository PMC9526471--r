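# shared fixtures: a fast reduced-scale configuration for module tests and
# a memoized full-scale pipeline run reused by the acceptance checks

small_cfg <- function(seed = 42, n_signature = 25, n_cassette = 10, ...) {
  sim_config(n_genes = 400, n_signature = n_signature,
             n_cassette = n_cassette,
             cohort_sizes = list(train_fnab = c(mtc = 8, non_mtc = 40),
                                 tissue = c(mtc = 6, non_mtc = 12),
                                 valid_fnab = c(mtc = 6, non_mtc = 20)),
             n_control_groups = 4, n_control_replicates = 3,
             seed = seed, ...)
}

# full study-scale run (default sim_config), computed once per test session
full_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_mtc_pipeline(sim_config(seed = 101))
    }
    cache
  }
})

# brute-force BH step-up: independent of the package implementation
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  sp <- p[o]
  adj <- numeric(n)
  for (k in seq_len(n)) {
    adj[k] <- min(1, min(n * sp[k:n] / (k:n)))
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# brute-force median-of-ratios, written independently of size_factors()
size_factor_oracle <- function(m) {
  geo <- apply(m, 1, function(r) exp(mean(log(r))))
  ok <- geo > 0 & is.finite(geo)
  sf <- apply(m, 2, function(cnts) {
    ratios <- (cnts / geo)[ok & cnts > 0]
    median(ratios)
  })
  sf / exp(mean(log(sf)))
}
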