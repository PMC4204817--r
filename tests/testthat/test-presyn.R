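test_that("renewal trains respect the interval floor, rate and regularity", {
  spec <- renewal_spec(duration = 100)
  seeds <- 1:50
  trains <- lapply(seeds, function(s) sample_renewal_train(spec, seed = s))
  isi <- unlist(lapply(trains, diff))
  # hard floor holds for every interval
  expect_true(min(isi) >= 0.010)
  # pooled rate near 5 Hz (resampling depresses it by < 1%)
  rate <- sum(lengths(trains)) / (50 * 100)
  sem <- stats::sd(lengths(trains) / 100) / sqrt(50)
  expect_lt(abs(rate - 5), 3 * sem + 0.05)
  # shape-2 renewal: ISI CV^2 near 1/2, mildly reduced by resampling
  cv2 <- stats::var(isi) / mean(isi)^2
  expect_lt(abs(cv2 - 0.5), 0.05)
  # all spikes inside [0, duration], strictly increasing
  expect_true(all(vapply(trains, function(tr)
    all(tr >= 0 & tr <= 100) && all(diff(tr) > 0), logical(1))))
})

test_that("degenerate and invalid renewal specs are handled", {
  expect_identical(
    sample_renewal_train(renewal_spec(duration = 0), seed = 1), numeric(0))
  expect_error(renewal_spec(shape = 0))
  expect_error(renewal_spec(rate = -1))
  expect_error(renewal_spec(min_isi = -1))
  expect_equal(renewal_spec()$scale_ms, 100)
})

test_that("ML gamma shape on resampled ISIs matches the truncated-gamma oracle", {
  # Oracle: numeric integration of the left-truncated Gamma(2, 100 ms)
  # moments at the 10 ms floor, solved through the gamma ML score
  # equation log(k) - digamma(k) = log(E[X]) - E[log X]:
  #   E[X | X >= c] = 0.2009091 s, E[log X | X >= c] = -1.864586
  #   => asymptotic fitted shape 2.07669 (the rejection floor removes the
  #      left tail, so the fitted shape sits ~3.8% above the nominal 2).
  oracle_shape <- 2.07669
  spec <- renewal_spec(duration = 150)
  trains <- lapply(100 + 1:60, function(s) sample_renewal_train(spec, seed = s))
  fit <- fit_isi_gamma(trains)
  expect_gt(fit[["n"]], 4e4)
  expect_lt(abs(fit[["shape"]] - oracle_shape) / oracle_shape, 0.02)
})

test_that("log-normal discretization reproduces the target log-moments", {
  d <- discretize_lognormal(amplitude_dist())
  expect_length(d$levels, 32)
  expect_equal(sum(d$probs), 1)
  expect_true(all(diff(d$levels) > 0))
  # log-spacing: equal steps in log space
  expect_equal(stats::sd(diff(log(d$levels))), 0, tolerance = 1e-12)
  # oracle: weighted moments by direct summation over the bin masses
  m <- sum(d$probs * log(d$levels))
  s <- sqrt(sum(d$probs * (log(d$levels) - m)^2))
  expect_lt(abs(m - 0.702) / 0.702, 0.02)
  expect_lt(abs(s - 0.9355) / 0.9355, 0.02)
})

test_that("degenerate discretization collapses to the median", {
  d <- discretize_lognormal(amplitude_dist(n_levels = 1))
  expect_equal(d$levels, exp(0.702))
  expect_equal(d$probs, 1)
  expect_error(amplitude_dist(n_levels = 0))
  expect_error(amplitude_dist(sigma_log = 0))
})

test_that("population has the configured E/I split and discrete amplitudes", {
  pop <- build_population(1024, 0.5, renewal_spec(duration = 2),
                          amplitude_dist(), seed = 7)
  expect_equal(sum(pop$roster$sign == "E"), 512)
  expect_equal(sum(pop$roster$sign == "I"), 512)
  lv <- discretize_lognormal(amplitude_dist())$levels
  expect_true(all(pop$roster$amplitude_pA %in% lv))
  expect_true(all(pop$roster$amplitude_pA > 0))
  # E and I amplitudes are drawn from the same discrete levels
  expect_true(all(pop$roster$amplitude_pA[pop$roster$sign == "E"] %in% lv))
  expect_true(all(pop$roster$amplitude_pA[pop$roster$sign == "I"] %in% lv))
  tiny <- build_population(2, 0.5, renewal_spec(duration = 1),
                           amplitude_dist(), seed = 1)
  expect_equal(c(sum(tiny$roster$sign == "E"), sum(tiny$roster$sign == "I")),
               c(1L, 1L))
  expect_error(build_population(3, 0.5, renewal_spec(duration = 1)))
})

test_that("populations are reproducible and trains regenerable per episode", {
  a <- build_population(16, 0.5, renewal_spec(duration = 5), seed = 11)
  b <- build_population(16, 0.5, renewal_spec(duration = 5), seed = 11)
  expect_identical(a, b)
  r1 <- regenerate_trains(a, 99)
  r2 <- regenerate_trains(a, 99)
  expect_identical(r1$trains, r2$trains)
  expect_identical(r1$roster, a$roster)
  expect_false(identical(r1$trains, a$trains))
})

test_that("stratified amplitude sampling apportions levels by probability", {
  d <- amplitude_dist()
  s <- sample_amplitudes(d, 512, seed = 3, stratified = TRUE)
  disc <- discretize_lognormal(d)
  cnt <- tabulate(s$class, nbins = 32)
  expect_true(all(abs(cnt - disc$probs * 512) <= 1))
})
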