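# Small-population settings for fast unit runs, and a cache so expensive
# Monte-Carlo experiments are computed once per test session.

small_run <- function(scenario = "status_quo", sensitivity = "none",
                      n_agents = 2000, years = 1, seed = 1, ...) {
  run_simulation(scenario, sensitivity, n_agents = n_agents, years = years,
                 seed = seed, ...)
}

.exp_cache <- new.env(parent = emptyenv())

cached_experiment <- function(key, expr) {
  if (is.null(.exp_cache[[key]])) .exp_cache[[key]] <- force(expr)
  .exp_cache[[key]]
}
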