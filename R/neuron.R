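#' Model-neuron parameters
#'
#' A leaky integrate-and-fire (LIF) neuron serving as the desk-scale
#' stand-in for the patch-clamped layer-2/3 pyramidal cell: it converts
#' injected current traces into membrane-potential traces and spike
#' times. Defaults are textbook cortical-pyramidal values tuned so that
#' fluctuating input currents with SD near 100 pA evoke
#' membrane-potential fluctuations of 15-20 mV amplitude. No claim of
#' quantitative equivalence to any real cell is made.
#'
#' Because a plain LIF has no action-potential overshoot, [simulate_neuron()]
#' pastes a stylized 2 ms triangular spike waveform (peak `spike_peak`)
#' into the voltage trace at each spike, so that the positive
#' zero-crossing detection rule of [detect_spikes()] works end-to-end.
#'
#' @param tau_m Membrane time constant, ms. Default 20.
#' @param r_in Input resistance, MOhm. Default 140.
#' @param v_rest Resting potential, mV. Default -70.
#' @param v_thresh Spike threshold, mV. Default -50.
#' @param v_reset Post-spike reset, mV. Default -60.
#' @param t_ref Absolute refractory period, ms. Default 3.
#' @param spike_peak Peak of the pasted spike waveform, mV. Default +30.
#' @return Object of class `neuron_params`.
#' @export
neuron_params <- function(tau_m = 20, r_in = 140, v_rest = -70,
                          v_thresh = -50, v_reset = -60, t_ref = 3,
                          spike_peak = 30) {
  if (!(v_thresh > v_reset)) stop("need v_thresh > v_reset")
  if (tau_m <= 0 || t_ref < 0 || r_in <= 0)
    stop("time constants and input resistance must be positive")
  structure(list(tau_m = tau_m, r_in = r_in, v_rest = v_rest,
                 v_thresh = v_thresh, v_reset = v_reset, t_ref = t_ref,
                 spike_peak = spike_peak),
            class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf(
    "LIF neuron: tau_m %g ms, R_in %g MOhm, rest %g mV, threshold %g mV, reset %g mV, refractory %g ms\n",
    x$tau_m, x$r_in, x$v_rest, x$v_thresh, x$v_reset, x$t_ref))
  invisible(x)
}

# Paste a stylized triangular spike (1 ms up to spike_peak, 1 ms down to
# v_reset) at each spike index so zero-crossing detection is exercisable.
paste_spike_waveform <- function(v, spike_idx, dt, params) {
  if (!length(spike_idx)) return(v)
  n_half <- max(1L, as.integer(round(1 / dt)))
  up <- seq(params$v_thresh, params$spike_peak, length.out = n_half + 1L)[-1L]
  down <- seq(params$spike_peak, params$v_reset,
              length.out = n_half + 1L)[-1L]
  shape <- c(up, down)
  n <- length(v)
  for (s in spike_idx) {
    j <- s + seq_along(shape) - 1L
    ok <- j <= n
    v[j[ok]] <- shape[ok]
  }
  v
}

#' Simulate the model neuron's response to an injected current
#'
#' Exponential-Euler integration of the LIF equation at the current
#' trace's sampling step; deterministic given its inputs (the model has
#' no intrinsic noise — all variability comes from the injected current).
#' Spikes are registered at threshold crossing, the voltage is reset and
#' held for the refractory period, and a stylized spike waveform is
#' pasted into the returned voltage trace.
#'
#' @param params A [neuron_params()].
#' @param current A [current_trace()].
#' @return List with `voltage` (mV, same length as the current),
#'   `spike_times` (s, the integrator's registry), `dt` (ms) and `rate`
#'   (Hz over the whole trace).
#' @export
simulate_neuron <- function(params, current) {
  stopifnot(inherits(params, "neuron_params"),
            inherits(current, "current_trace"))
  if (!all(is.finite(current$samples))) stop("current contains non-finite values")
  res <- .lif_integrate(current$samples, current$dt, params$tau_m,
                        params$r_in, params$v_rest, params$v_thresh,
                        params$v_reset, params$t_ref)
  spike_idx <- res$spike_idx
  v <- paste_spike_waveform(res$voltage, spike_idx, current$dt, params)
  duration <- length(current$samples) * current$dt / 1000
  spike_times <- (spike_idx - 1L) * current$dt / 1000
  list(voltage = v, spike_times = spike_times, dt = current$dt,
       rate = length(spike_times) / duration)
}

#' Detect spikes as positive zero crossings of the membrane potential
#'
#' @param voltage Numeric vector, mV, uniformly sampled.
#' @param dt Sample interval, ms.
#' @param threshold Crossing level, mV. Default 0.
#' @return Spike times in seconds (one event per upward crossing).
#' @export
detect_spikes <- function(voltage, dt, threshold = 0) {
  n <- length(voltage)
  if (n < 2) return(numeric(0))
  below <- voltage[-n] < threshold
  above <- voltage[-1] >= threshold
  (which(below & above)) * dt / 1000
}

#' Closed-form firing rate of a LIF neuron under constant current
#'
#' For a constant suprathreshold current the LIF fires periodically at
#' `1 / (t_ref + tau_m * log((v_inf - v_reset)/(v_inf - v_thresh)))`
#' with `v_inf = v_rest + R * I`. Returns 0 below rheobase.
#'
#' @param params A [neuron_params()].
#' @param current_pA Constant current, pA.
#' @return Firing rate, Hz.
#' @export
lif_rate_constant_current <- function(params, current_pA) {
  v_inf <- params$v_rest + params$r_in * current_pA * 1e-3
  ifelse(v_inf <= params$v_thresh, 0,
         1000 / (params$t_ref + params$tau_m *
                   log((v_inf - params$v_reset) / (v_inf - params$v_thresh))))
}

# Firing rate (Hz) of a simulated response, excluding the discard window.
measured_rate <- function(spike_times, duration, discard = 0) {
  sum(spike_times >= discard) / (duration - discard)
}

#' Calibrate the DC offset to a target firing rate
#'
#' Emulates the experimental adjustment of the DC current: bisects the
#' DC offset added to a fixed template of fluctuating current until the
#' firing rate measured on the probe episode (excluding the discard
#' window) is within `tol` of `target_rate`. The LIF f-I curve is
#' monotone, so bisection converges; if the target is unreachable within
#' the bracket an error reports the achieved bracket.
#'
#' @param params A [neuron_params()].
#' @param template_current A [current_trace()] of zero-DC fluctuating
#'   current used as the probe episode.
#' @param target_rate Target firing rate, Hz (>= 0).
#' @param tol Absolute tolerance, Hz. Default 5% of the target (0.1 Hz
#'   minimum).
#' @param discard Initial window excluded from rate measurement, s.
#'   Default 2.
#' @param bracket Initial DC search interval, pA. Default c(-200, 400),
#'   widened upward automatically if too narrow.
#' @param max_iter Maximum bisection steps. Default 30.
#' @return List with `dc` (pA) and `achieved_rate` (Hz).
#' @export
calibrate_dc <- function(params, template_current, target_rate,
                         tol = max(0.05 * target_rate, 0.1), discard = 2,
                         bracket = c(-200, 400), max_iter = 30) {
  duration <- length(template_current$samples) * template_current$dt / 1000
  if (duration <= discard) stop("probe episode shorter than the discard window")
  rate_at <- function(dc) {
    cur <- template_current
    cur$samples <- cur$samples + dc
    cur$dc <- dc
    sim <- simulate_neuron(params, cur)
    measured_rate(sim$spike_times, duration, discard)
  }
  lo <- bracket[1]; hi <- bracket[2]
  r_lo <- rate_at(lo)
  if (r_lo > target_rate)
    stop(sprintf("lower bracket %g pA already fires at %.2f Hz > target %.2f Hz",
                 lo, r_lo, target_rate))
  if (target_rate == 0)
    return(list(dc = lo, achieved_rate = r_lo))
  r_hi <- rate_at(hi)
  tries <- 0
  while (r_hi < target_rate && tries < 6) {
    hi <- hi + diff(range(bracket))
    r_hi <- rate_at(hi)
    tries <- tries + 1
  }
  if (r_hi < target_rate)
    stop(sprintf(
      "target %.2f Hz unreachable: bracket [%g, %g] pA achieves [%.2f, %.2f] Hz",
      target_rate, lo, hi, r_lo, r_hi))
  mid <- NA_real_; r_mid <- NA_real_
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r_mid <- rate_at(mid)
    if (abs(r_mid - target_rate) <= tol) break
    if (r_mid > target_rate) hi <- mid else lo <- mid
  }
  if (abs(r_mid - target_rate) > tol)
    warning(sprintf("calibration stopped at %.2f Hz for target %.2f Hz",
                    r_mid, target_rate))
  list(dc = mid, achieved_rate = r_mid)
}

#' Amplitude of membrane-potential fluctuations
#'
#' Quantifies subthreshold fluctuation amplitude as the 5th-95th
#' percentile range of the voltage trace with spike-affected samples
#' removed (from each spike onset to the end of the pasted waveform plus
#' refractory period).
#'
#' @param sim A [simulate_neuron()] result.
#' @param params The [neuron_params()] used.
#' @return Fluctuation amplitude, mV.
#' @export
voltage_fluctuation_amplitude <- function(sim, params) {
  v <- sim$voltage
  if (length(sim$spike_times)) {
    dt <- sim$dt
    mask_len <- as.integer(round((2 + params$t_ref) / dt))
    bad <- unlist(lapply(sim$spike_times, function(ts) {
      i0 <- as.integer(round(ts * 1000 / dt)) + 1L
      i0:min(i0 + mask_len, length(v))
    }))
    v <- v[-unique(bad)]
  }
  unname(diff(stats::quantile(v, c(0.05, 0.95))))
}

#' Run a protocol of repeated current-injection episodes
#'
#' Reproduces the episode structure of the recording protocol: a series
#' of `n_episodes` injections of `episode_s` seconds each. For each
#' episode a fresh realization of every presynaptic neuron's spike train
#' is drawn (the roster of signs and amplitudes stays fixed), the mixture
#' current is synthesized and scaled to `target_sd`, the calibrated DC is
#' added, and the model neuron is simulated. Spikes in the first
#' `discard_s` seconds are excluded from analysis (initial-transient
#' discard); per-episode firing rates are also logged in 5 s bins.
#'
#' @param params A [neuron_params()].
#' @param pop A [build_population()] result (roster defines the inputs).
#' @param kernel A [psc_kernel()].
#' @param n_episodes Number of episodes.
#' @param dc DC offset, pA (from [calibrate_dc()]).
#' @param episode_s Episode duration, s. Default 46.
#' @param discard_s Discard window, s. Default 2.
#' @param target_sd Target current SD, pA. Default 100.
#' @param seed Master seed; episode substreams are derived from it.
#' @param keep_voltage Keep the full voltage traces (memory!). Default FALSE.
#' @return Object of class `episode_set`: list of episodes (each with
#'   `spike_times` from zero-crossing detection, `triggers`,
#'   `scale_factor`, `rate`, `rate_bins_5s`, optionally `voltage`), plus
#'   protocol metadata.
#' @export
run_episodes <- function(params, pop, kernel, n_episodes, dc,
                         episode_s = 46, discard_s = 2, target_sd = 100,
                         seed = 1L, keep_voltage = FALSE) {
  eseeds <- substream_seeds(seed, n_episodes)
  episodes <- vector("list", n_episodes)
  for (e in seq_len(n_episodes)) {
    pe <- regenerate_trains(pop, eseeds[e], duration = episode_s)
    mix <- synthesize_mixture(pe, kernel, target_sd = target_sd, dc = dc,
                              duration = episode_s)
    sim <- simulate_neuron(params, mix$trace)
    spikes <- detect_spikes(sim$voltage, sim$dt)
    bins <- seq(0, episode_s, by = 5)
    rate_bins <- as.numeric(table(cut(spikes, bins))) / 5
    episodes[[e]] <- list(
      spike_times = spikes,
      triggers = mix$triggers,
      scale_factor = mix$scale_factor,
      rate = measured_rate(spikes, episode_s, discard_s),
      rate_bins_5s = rate_bins,
      seed = eseeds[e],
      voltage = if (keep_voltage) sim$voltage else NULL)
  }
  structure(
    list(episodes = episodes, episode_s = episode_s, discard_s = discard_s,
         dc = dc, target_sd = target_sd, params = params, seed = seed),
    class = "episode_set")
}

#' @export
print.episode_set <- function(x, ...) {
  rates <- vapply(x$episodes, `[[`, numeric(1), "rate")
  cat(sprintf(
    "Episode set: %d episodes x %g s (discard %g s), DC %.1f pA, mean rate %.2f Hz\n",
    length(x$episodes), x$episode_s, x$discard_s, x$dc, mean(rates)))
  invisible(x)
}
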