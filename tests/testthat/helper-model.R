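# Shared model-neuron pipeline for the acceptance tests: one defined
# 1024-neuron population (fixed roster across firing-rate conditions, as
# for a single recorded cell), DC calibrated per target rate, repeated
# 46 s episodes, sweeps pooled into 8 amplitude bins (4 adjacent
# log-levels each) for statistical stability. Built lazily and cached so
# several test files can share one simulation.
.model_cache <- new.env(parent = emptyenv())

amp_bins8 <- function(cls, amp) pmin((cls - 1L) %/% 4L + 1L, 8L)

model_run <- function(rate = 5, n_episodes = if (rate == 5) 10L else 6L) {
  key <- sprintf("rate%g", rate)
  if (!is.null(.model_cache[[key]])) return(.model_cache[[key]])
  np <- neuron_params()
  kern <- psc_kernel(0.5, 5)
  pop <- build_population(1024, 0.5,
                          renewal = renewal_spec(duration = 46),
                          dist = amplitude_dist(), seed = 20140101L)
  probe <- synthesize_mixture(regenerate_trains(pop, 555L, duration = 46),
                              kern, target_sd = 100, duration = 46)
  cal <- calibrate_dc(np, probe$trace, rate, discard = 2)
  eps <- run_episodes(np, pop, kern, n_episodes, cal$dc,
                      episode_s = 46, discard_s = 2, target_sd = 100,
                      seed = 7000L + round(rate))
  sweeps <- collect_sweeps(eps, T_max = 15, class_of = amp_bins8)
  out <- list(params = np, kernel = kern, pop = pop, cal = cal,
              episodes = eps, sweeps = sweeps)
  .model_cache[[key]] <- out
  out
}
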