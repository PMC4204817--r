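test_that("PSC kernel peaks at the closed-form time with unit amplitude", {
  k <- psc_kernel(0.5, 5, 0.05)
  t_star <- 0.5 * 5 / (5 - 0.5) * log(5 / 0.5)
  expect_equal(k$t_peak, t_star)
  expect_equal(k$times[which.max(k$waveform)], t_star, tolerance = 0.05)
  expect_equal(max(k$waveform), 1)
  expect_equal(k$waveform[1], 0)
  k2 <- psc_kernel(1, 10, 0.05)
  expect_equal(k2$t_peak, 1 * 10 / 9 * log(10), tolerance = 1e-12)
  expect_equal(k2$times[which.max(k2$waveform)], 2.558, tolerance = 0.05)
  # template truncated only once negligible
  expect_lt(k$waveform[length(k$waveform)], 1.1e-4)
  expect_error(psc_kernel(5, 5))
  expect_error(psc_kernel(6, 5))
})

test_that("PSC rendering superposes kernels exactly and linearly", {
  k <- psc_kernel(0.5, 5, 0.05)
  dur <- 0.5
  # single onset: peak value = amplitude at t0 + t*
  tr <- render_psc_train(k, 0.1, amplitude = 40, duration = dur)
  i_peak <- which.max(tr$samples)
  expect_equal(max(tr$samples), 40, tolerance = 1e-6)
  expect_lt(abs((i_peak - 1) * 0.05 / 1000 - (0.1 + k$t_peak / 1000)), 1e-4)
  # empty onsets give a zero trace
  expect_equal(render_psc_train(k, numeric(0), 40, dur)$samples,
               rep(0, dur * 1000 / 0.05))
  # union-vs-sum equality on random onset sets
  set.seed(5)
  on_a <- sort(stats::runif(7, 0, dur - 0.06))
  on_b <- sort(stats::runif(5, 0, dur - 0.06))
  both <- render_psc_train(k, c(on_a, on_b), 10, dur)$samples
  apart <- render_psc_train(k, on_a, 10, dur)$samples +
    render_psc_train(k, on_b, 10, dur)$samples
  expect_equal(both, apart, tolerance = 1e-10)
  # brute-force superposition oracle with the sampled (truncated) template
  n <- length(both)
  brute <- numeric(n)
  for (t0 in c(on_a, on_b)) {
    i0 <- round(t0 * 1000 / 0.05) + 1
    j <- i0:min(i0 + length(k$waveform) - 1, n)
    brute[j] <- brute[j] + 10 * k$waveform[seq_along(j)]
  }
  expect_equal(both, brute, tolerance = 1e-3)
})

test_that("OU generator matches its stationary moments and autocorrelation", {
  for (dt in c(0.05, 0.5)) {
    ou <- generate_ou(ou_spec(2, 5, dt), duration = 100, seed = 17)
    n_eff <- 100 / (2 * 0.005)  # independent stretches of ~2 tau
    expect_equal(stats::sd(ou$samples), 2, tolerance = 4 / sqrt(2 * n_eff))
    expect_lt(abs(mean(ou$samples)), 4 * 2 * sqrt(2 * 0.005 / 100))
    lag <- round(5 / dt)
    ac <- stats::acf(ou$samples, lag.max = lag, plot = FALSE)$acf
    expect_equal(ac[lag + 1], exp(-1), tolerance = 0.04)
  }
  expect_equal(generate_ou(ou_spec(0, 5), 1, seed = 1)$samples,
               rep(0, 1000 / 0.05))
  expect_error(ou_spec(-1, 5))
  expect_error(ou_spec(1, 0))
})

test_that("signal-in-noise current is the exact sum of its components", {
  ou <- ou_spec(110, 5, 0.05)
  k <- psc_kernel(1, 10, 0.05)
  onsets <- c(0.2, 0.45, 0.8)
  syn <- synthesize_signal_in_noise(ou, k, 50, onsets, dc = 30,
                                    duration = 1, seed = 23)
  noise <- generate_ou(ou, 1, seed = 23)
  sig <- render_psc_train(k, onsets, 50, 1)
  expect_equal(syn$trace$samples, noise$samples + sig$samples + 30,
               tolerance = 1e-12)
  expect_equal(syn$triggers$onset_time_s, onsets)
  expect_true(all(syn$triggers$sign == "E"))
  # dc-only degenerate case: sigma = 0, no onsets -> constant trace
  flat <- synthesize_signal_in_noise(ou_spec(0, 5, 0.05), k, 50,
                                     numeric(0), dc = 12, duration = 0.1)
  expect_true(all(flat$trace$samples == 12))
  # inhibitory signal carries sign "I"
  syn_i <- synthesize_signal_in_noise(ou, k, -50, onsets, duration = 1,
                                      seed = 3)
  expect_true(all(syn_i$triggers$sign == "I"))
})

test_that("mixture synthesis scales to target SD and stays linear", {
  kern <- psc_kernel(0.5, 5, 0.05)
  pop <- build_population(32, 0.5, renewal_spec(duration = 4), seed = 31)
  mix <- synthesize_mixture(pop, kern, target_sd = 100, dc = 25, duration = 4)
  expect_equal(stats::sd(mix$trace$samples - 25), 100, tolerance = 1e-9)
  expect_equal(mix$trace$dc, 25)
  # trigger table records every presynaptic spike with scaled amplitude
  expect_equal(nrow(mix$triggers), sum(lengths(pop$trains)))
  expect_equal(sort(mix$triggers$onset_time_s),
               sort(unlist(pop$trains)), tolerance = 1e-12)
  expect_equal(sort(unique(mix$triggers$amplitude_pA / mix$scale_factor)),
               sort(unique(pop$roster$amplitude_pA)), tolerance = 1e-12)
  # superposition: the unscaled sum equals the sum of per-neuron renders
  raw <- (mix$trace$samples - 25) / mix$scale_factor
  manual <- numeric(length(raw))
  for (i in seq_len(nrow(pop$roster))) {
    s <- if (pop$roster$sign[i] == "E") 1 else -1
    manual <- manual + s * render_psc_train(
      kern, pop$trains[[i]], pop$roster$amplitude_pA[i], 4)$samples
  }
  expect_equal(raw, manual, tolerance = 1e-9)
  # one-neuron population reduces to a scaled single-train render
  solo <- build_population(1, 1, renewal_spec(duration = 4), seed = 32)
  mix1 <- synthesize_mixture(solo, kern, target_sd = 50, duration = 4)
  ref <- render_psc_train(kern, solo$trains[[1]],
                          solo$roster$amplitude_pA[1], 4)$samples
  expect_equal(mix1$trace$samples, ref * mix1$scale_factor, tolerance = 1e-9)
  expect_error(synthesize_mixture(
    structure(list(roster = data.frame()), class = "presyn_population"),
    kern))
})
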