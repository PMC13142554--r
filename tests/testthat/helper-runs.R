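# Long forward runs are shared across test files via a session cache.
# All use the reference parameter set, the seeded-colony initial condition,
# seed 1 and the 100x100 default grid.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(gamma, t_end = 180, scheme = "arithmetic",
                       traces = FALSE) {
  key <- sprintf("g%s_t%s_%s_%d", gamma, t_end, scheme, traces)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  cfg <- sim_config(ks_params(gamma = gamma), t_end = t_end, seed = 1,
                    snapshot_times = c(0, 2.5, 7.8, 19.2, 46.3, 90, t_end),
                    scheme = scheme,
                    trace_positions = if (traces)
                      list(c(50, 50), c(52, 50), c(54, 50)) else NULL)
  .run_cache[[key]] <- simulate_ks(cfg)
  .run_cache[[key]]
}
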