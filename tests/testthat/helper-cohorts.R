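# Shared simulated cohorts, built once per test run.  The recovery cohort
# (planted introgression, sweeps and IBD tracts) is expensive, so derived
# products are cached alongside it.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cohort_cache)) {
    assign(key, force(expr), envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}

recovery_sim <- function() {
  cached("recovery", simulate_cohort(benchmark_config("recovery", seed = 1)))
}

null_sim <- function() {
  cached("null", simulate_cohort(benchmark_config("null", seed = 1)))
}

recovery_fd <- function() {
  cached("recovery_fd", {
    sim <- recovery_sim()
    wins <- make_windows(sim$genotypes$layout, 5e4, 5e4)
    fd_windows(sim$genotypes, quartet_spec(), wins)
  })
}

recovery_ancestry <- function() {
  cached("recovery_ancestry", {
    sim <- recovery_sim()
    wins <- make_windows(sim$genotypes$layout, 5e4, 5e4)
    ancestry_window_fractions(naive_paint(sim$genotypes), wins)
  })
}

recovery_ibd <- function() {
  cached("recovery_ibd", {
    g <- recovery_sim()$genotypes
    list(eu = naive_ibd(g, "B", "EU"), as = naive_ibd(g, "B", "AS"))
  })
}
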