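test_that("sweep collection aligns spikes and applies exclusions", {
  spikes <- data.frame(episode_id = 1, time_s = c(0.5, 10.003, 10.020))
  triggers <- data.frame(episode_id = 1, neuron_id = c(1L, 2L),
                         sign = "E", amplitude_pA = 50, amplitude_class = 1L,
                         onset_time_s = c(1.0, 10.0))
  eps <- as_episode_set(spikes, triggers, episode_s = 20, discard_s = 2)
  sw <- collect_sweeps(eps, T_max = 15)
  # the trigger at 1 s sits inside the discard window -> excluded
  expect_equal(sum(sw$groups$n_sweeps), 1)
  # only the +3 ms spike falls inside the +/-15 ms window
  expect_equal(sw$events$rel_ms, 3, tolerance = 1e-9)
  # a trigger too close to the episode end is excluded as well
  trg2 <- rbind(triggers,
                data.frame(episode_id = 1, neuron_id = 3L, sign = "E",
                           amplitude_pA = 50, amplitude_class = 1L,
                           onset_time_s = 19.995))
  sw2 <- collect_sweeps(as_episode_set(spikes, trg2, 20, 2), T_max = 15)
  expect_equal(sum(sw2$groups$n_sweeps), 1)
})

test_that("sweep counts scale with rate, duration and neurons per class", {
  pop <- build_population(40, 0.5, renewal_spec(duration = 30), seed = 67)
  mix <- synthesize_mixture(pop, psc_kernel(0.5, 5), 100, duration = 30)
  eps <- structure(list(
    episodes = list(list(spike_times = numeric(0), triggers = mix$triggers,
                         scale_factor = mix$scale_factor, rate = 0)),
    episode_s = 30, discard_s = 2, dc = 0, target_sd = 100, params = NULL,
    seed = 1), class = "episode_set")
  sw <- collect_sweeps(eps, T_max = 15, class_of = function(cls, amp) 1L)
  # direct count oracle: triggers in the analyzed span, ~ rate * span * N
  span <- 30 - 2 - 2 * 0.015
  n_expected <- 5 * span * 40
  expect_lt(abs(sum(sw$groups$n_sweeps) - n_expected) / n_expected, 0.1)
})

test_that("PSTH is flat without signal and conserves spike counts", {
  set.seed(71)
  # uniform random spikes at 20 Hz, unrelated to triggers
  spikes <- data.frame(episode_id = 1,
                       time_s = sort(stats::runif(2000, 0, 100)))
  triggers <- data.frame(episode_id = 1, neuron_id = 1L, sign = "E",
                         amplitude_pA = 10, amplitude_class = 1L,
                         onset_time_s = sort(stats::runif(400, 3, 97)))
  eps <- as_episode_set(spikes, triggers, episode_s = 100, discard_s = 2)
  sw <- collect_sweeps(eps, T_max = 15)
  ps <- build_psth(sw, bin = 5)
  expect_equal(sum(ps$count), nrow(sw$events))
  expect_equal(mean(ps$rate_hz), 20, tolerance = 0.2)
  expect_lt(stats::sd(ps$rate_hz) / mean(ps$rate_hz), 0.35)
})

test_that("window probabilities match manual enumeration on a toy set", {
  # 10 sweeps: post-window spikes in sweeps 1-3 (at +2 ms), pre-window
  # spikes in sweeps 1 and 4 (at -4 ms), plus one far spike outside T
  ev <- data.frame(group = 1L, sign = "E",
                   sweep = c(1L, 2L, 3L, 1L, 4L, 5L),
                   rel_ms = c(2, 2, 2, -4, -4, 9))
  sw <- structure(list(
    events = ev,
    groups = data.frame(sign = "E", group = 1L, amplitude_pA = 1,
                        amplitude_sd = 0.01, n_sweeps = 10L),
    T_max = 10), class = "triggered_sweeps")
  wp <- window_probs(sw, T = 5)
  expect_equal(wp$P_post, 0.3)
  expect_equal(wp$P_pre, 0.2)
  expect_equal(wp$P_post_count, 0.3)
  expect_equal(wp$P_pre_count, 0.2)
  # widen the window: the +9 ms spike joins the post count
  expect_equal(window_probs(sw, 10)$P_post, 0.4)
  # degenerate cases
  none <- sw; none$events <- ev[0, ]
  expect_equal(window_probs(none, 5)$P_pre, 0)
  expect_equal(window_probs(none, 5)$P_post, 0)
  expect_error(window_probs(sw, 20), "T_max")
})

test_that("parametric detection matches the brute-force binomial oracle", {
  grid <- expand.grid(N = c(250, 500, 1000, 2000),
                      p_pre = c(0.001, 0.005, 0.02),
                      p_post = c(0.001, 0.004, 0.02, 0.08),
                      sign = c("E", "I"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_lt(abs(parametric_detection(g$p_pre, g$p_post, g$N, g$sign) -
                    brute_force_detection(g$p_pre, g$p_post, g$N, g$sign)),
              1e-10)
  }
  # Poisson-limit cross-check: lambda 1 vs 3, threshold q = 3
  q <- min(which(stats::ppois(0:20, 1) >= 0.95)) - 1
  expect_equal(q, 3)
  pois <- 1 - stats::ppois(q, 3)
  expect_equal(parametric_detection(0.001, 0.003, 1000, "E"), pois,
               tolerance = 0.01)
  # certain detection and null calibration
  expect_equal(parametric_detection(0, 1, 500, "E"), 1)
  p_null <- parametric_detection(c(0.001, 0.01, 0.05), c(0.001, 0.01, 0.05),
                                 1000, "E")
  expect_true(all(p_null <= 0.05))
})

test_that("parametric detection grows with N when P_post exceeds P_pre", {
  # non-strict: the integer decoder threshold makes small plateaus possible
  det <- parametric_detection(0.002, 0.004, c(250, 500, 1000, 2000), "E")
  expect_true(all(diff(det) >= 0))
  expect_gt(det[4], det[1])
  det_i <- parametric_detection(0.004, 0.002, c(250, 500, 1000, 2000), "I")
  expect_true(all(diff(det_i) >= 0))
  expect_gt(det_i[4], det_i[1])
})

test_that("bootstrap detection agrees with the parametric formula", {
  for (case in list(list(p_pre = 0.005, p_post = 0.015, sign = "E"),
                    list(p_pre = 0.015, p_post = 0.005, sign = "I"))) {
    sw <- make_bernoulli_sweeps(40000, case$p_pre, case$p_post,
                                sign = case$sign, seed = 83)
    wp <- window_probs(sw, 10)
    par_det <- parametric_detection(wp$P_pre, wp$P_post, 1000, case$sign)
    b <- bootstrap_detection(sw, 10, 1000, case$sign, 1L,
                             n_sets = 100, n_reps = 30, seed = 89)
    expect_lt(abs(b[["detection"]] - par_det), 0.05)
  }
  # null case: identical pre/post statistics
  sw0 <- make_bernoulli_sweeps(40000, 0.01, 0.01, seed = 97)
  b0 <- bootstrap_detection(sw0, 10, 500, "E", 1L, n_sets = 100,
                            n_reps = 30, seed = 101)
  expect_lte(b0[["detection"]],
             0.05 + 3 * max(b0[["dispersion"]], sqrt(0.05 * 0.95 / 100)))
  # reproducibility
  b1 <- bootstrap_detection(sw0, 10, 500, "E", 1L, n_sets = 20, n_reps = 5,
                            seed = 7)
  b2 <- bootstrap_detection(sw0, 10, 500, "E", 1L, n_sets = 20, n_reps = 5,
                            seed = 7)
  expect_identical(b1, b2)
  expect_error(bootstrap_detection(sw0, 10, 500, "E", 1L, n_sets = 100,
                                   n_reps = 2, replace = FALSE))
})

test_that("parametric surface is monotone in T for cumulative responses", {
  # synthetic sweeps: post-onset spikes uniform in [0, 8] ms with overall
  # probability 0.04, pre-onset baseline 0.01 -> P_post(T) - P_pre(T)
  # non-decreasing in T, so detection must be non-decreasing too
  set.seed(103)
  n <- 50000
  post_hit <- which(stats::runif(n) < 0.04)
  pre_hit <- which(stats::runif(n) < 0.01)
  sw <- structure(list(
    events = data.frame(
      group = 1L, sign = "E",
      sweep = c(post_hit, pre_hit),
      rel_ms = c(stats::runif(length(post_hit), 0, 8),
                 stats::runif(length(pre_hit), -10, 0))),
    groups = data.frame(sign = "E", group = 1L, amplitude_pA = 1,
                        amplitude_sd = 0.5, n_sweeps = n),
    T_max = 10), class = "triggered_sweeps")
  surf <- detection_surface(sw, T_grid = c(1, 2, 4, 6, 8), N_list = c(500),
                            method = "parametric")
  expect_true(all(surf$detection >= 0 & surf$detection <= 1))
  expect_true(all(diff(surf$detection[order(surf$T_ms)]) >= -1e-12))
})

test_that("circularly shifted triggers keep marginals but lose alignment", {
  pop <- build_population(16, 0.5, renewal_spec(duration = 10), seed = 107)
  eps <- run_episodes(neuron_params(), pop, psc_kernel(0.5, 5), 2, dc = 100,
                      episode_s = 10, discard_s = 2, seed = 109)
  sh <- shift_triggers(eps, seed = 3)
  for (i in 1:2) {
    a <- eps$episodes[[i]]$triggers; b <- sh$episodes[[i]]$triggers
    expect_equal(nrow(a), nrow(b))
    expect_equal(sort(a$amplitude_pA), sort(b$amplitude_pA))
    expect_false(isTRUE(all.equal(sort(a$onset_time_s),
                                  sort(b$onset_time_s))))
    expect_true(all(b$onset_time_s >= 2 & b$onset_time_s <= 10))
  }
})
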