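#' Difference-of-exponentials PSC kernel
#'
#' The postsynaptic current elicited by one presynaptic spike is modelled
#' as a difference of two exponentials,
#' `w(t) = exp(-t/tau_decay) - exp(-t/tau_rise)`, normalized to unit peak
#' so that a PSC's "amplitude" in pA equals its peak current. The two
#' parameters are the exponential time constants themselves (not 10-90%
#' rise/decay times). The analytic peak time is
#' `t* = tau_rise*tau_decay/(tau_decay - tau_rise) * log(tau_decay/tau_rise)`.
#'
#' The stored waveform template is sampled on the `dt` grid and truncated
#' where the unit-peak waveform falls below 1e-4 (about nine decay time
#' constants); rendering with [render_psc_train()] uses the exact
#' recursive form of the two exponentials and is not truncated.
#'
#' @param tau_rise Rise time constant, ms. Default 0.5 (mixture paradigm;
#'   the signal-in-noise paradigm uses 1).
#' @param tau_decay Decay time constant, ms; must exceed `tau_rise`.
#'   Default 5 (signal-in-noise: 10).
#' @param dt Sample interval, ms. Default 0.05 (20 kHz acquisition grid).
#' @return Object of class `psc_kernel` with fields `tau_rise`,
#'   `tau_decay`, `dt`, `times` (ms), `waveform` (unit peak), `t_peak`
#'   (ms), `norm` (raw peak value used for normalization) and
#'   `kernel_length` (ms).
#' @examples
#' k <- psc_kernel(0.5, 5)
#' k$t_peak           # ~1.279 ms
#' max(k$waveform)    # 1
#' @export
psc_kernel <- function(tau_rise = 0.5, tau_decay = 5, dt = 0.05) {
  if (!(tau_decay > tau_rise && tau_rise > 0))
    stop("need tau_decay > tau_rise > 0")
  if (dt <= 0) stop("'dt' must be > 0")
  t_peak <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  raw <- function(t) exp(-t / tau_decay) - exp(-t / tau_rise)
  # truncate where the unit-peak waveform drops below 1e-4 (decay tail)
  peak_raw <- raw(t_peak)
  len_ms <- tau_decay * log(1 / (1e-4 * peak_raw)) + dt
  times <- seq(0, len_ms, by = dt)
  w <- raw(times)
  norm <- max(w)
  structure(
    list(tau_rise = tau_rise, tau_decay = tau_decay, dt = dt,
         times = times, waveform = w / norm, t_peak = t_peak, norm = norm,
         kernel_length = len_ms),
    class = "psc_kernel")
}

#' @export
print.psc_kernel <- function(x, ...) {
  cat(sprintf(
    "PSC kernel: rise %g ms, decay %g ms, peak at %.3f ms, %g ms template at dt = %g ms\n",
    x$tau_rise, x$tau_decay, x$t_peak, round(x$kernel_length, 1), x$dt))
  invisible(x)
}

#' Current trace container
#'
#' Uniformly sampled injected-current waveform in pA plus provenance.
#'
#' @param samples Numeric vector, pA.
#' @param dt Sample interval, ms.
#' @param dc DC offset already contained in `samples`, pA.
#' @param meta Named list of provenance (paradigm, seed, scale factor, ...).
#' @return Object of class `current_trace`.
#' @export
current_trace <- function(samples, dt, dc = 0, meta = list()) {
  if (!all(is.finite(samples))) stop("current samples must be finite")
  structure(list(samples = samples, dt = dt, dc = dc, meta = meta),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf(
    "Current trace: %d samples at dt = %g ms (%.3f s), SD %.2f pA, DC %.2f pA\n",
    length(x$samples), x$dt, length(x$samples) * x$dt / 1000,
    stats::sd(x$samples), x$dc))
  invisible(x)
}

#' Ornstein-Uhlenbeck noise specification
#'
#' Zero-mean Gaussian noise with exponential autocorrelation
#' `exp(-lag/tau_corr)`, the standard model of summed synaptic background
#' in the signal-immersed-in-noise paradigm.
#'
#' @param sigma Stationary standard deviation, pA (>= 0).
#' @param tau_corr Correlation time, ms (> 0). Default 5.
#' @param dt Sample interval, ms. Default 0.05.
#' @return Object of class `ou_spec`.
#' @export
ou_spec <- function(sigma, tau_corr = 5, dt = 0.05) {
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (tau_corr <= 0) stop("'tau_corr' must be > 0")
  structure(list(sigma = sigma, tau_corr = tau_corr, dt = dt),
            class = "ou_spec")
}

#' Generate an Ornstein-Uhlenbeck noise trace
#'
#' Uses the exact discretization of the OU process,
#' `x[n+1] = x[n] exp(-dt/tau) + sigma sqrt(1 - exp(-2 dt/tau)) xi[n]`,
#' started from its stationary distribution `N(0, sigma^2)`, so the
#' sampled process has exactly the target variance and autocorrelation
#' for any `dt`.
#'
#' @param spec An [ou_spec()].
#' @param duration Trace length, seconds (> 0).
#' @param seed Optional integer seed.
#' @return A [current_trace()].
#' @export
generate_ou <- function(spec, duration, seed = NULL) {
  stopifnot(inherits(spec, "ou_spec"))
  if (duration <= 0) stop("'duration' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * 1000 / spec$dt)
  if (spec$sigma == 0) {
    x <- numeric(n)
  } else {
    a <- exp(-spec$dt / spec$tau_corr)
    innov <- stats::rnorm(n, sd = spec$sigma * sqrt(1 - a^2))
    x0 <- stats::rnorm(1, sd = spec$sigma)
    x <- as.numeric(stats::filter(innov, a, method = "recursive", init = x0))
  }
  current_trace(x, spec$dt, dc = 0,
                meta = list(kind = "ou", sigma = spec$sigma,
                            tau_corr = spec$tau_corr, seed = seed))
}

# Map onset times (s) to 1-based sample indices on the dt (ms) grid.
onset_index <- function(onsets, dt, n) {
  idx <- as.integer(round(onsets * 1000 / dt)) + 1L
  idx[idx >= 1L & idx <= n]
}

# Exact superposition of difference-of-exponentials kernels: the delta
# train is run through two first-order recursive filters (one per
# exponential); identical to convolving with the untruncated kernel.
render_deltas <- function(delta, kernel) {
  a_d <- exp(-kernel$dt / kernel$tau_decay)
  a_r <- exp(-kernel$dt / kernel$tau_rise)
  out <- stats::filter(delta, a_d, method = "recursive") -
    stats::filter(delta, a_r, method = "recursive")
  as.numeric(out) / kernel$norm
}

#' Render a PSC train as a current trace
#'
#' Linear superposition of unit-peak kernels scaled by `amplitude` at
#' each onset. Onsets are snapped to the nearest sample on the `dt` grid.
#'
#' @param kernel A [psc_kernel()].
#' @param onsets Numeric vector of PSC onset times, seconds.
#' @param amplitude Peak amplitude, pA (one value, or one per onset).
#' @param duration Trace length, seconds.
#' @return A [current_trace()].
#' @export
render_psc_train <- function(kernel, onsets, amplitude, duration) {
  stopifnot(inherits(kernel, "psc_kernel"))
  n <- round(duration * 1000 / kernel$dt)
  delta <- numeric(n)
  if (length(onsets)) {
    if (any(onsets < 0 | onsets > duration))
      stop("onsets must lie within [0, duration]")
    amplitude <- rep_len(amplitude, length(onsets))
    idx <- as.integer(round(onsets * 1000 / kernel$dt)) + 1L
    keep <- idx >= 1L & idx <= n
    idx <- idx[keep]; amp <- amplitude[keep]
    if (length(idx)) {
      add <- rowsum(amp, idx)
      delta[as.integer(rownames(add))] <- add[, 1L]
    }
    samples <- render_deltas(delta, kernel)
  } else {
    samples <- delta
  }
  current_trace(samples, kernel$dt, dc = 0,
                meta = list(kind = "psc_train", n_onsets = length(onsets)))
}

#' Synthesize a signal-immersed-in-noise current
#'
#' First stimulation paradigm: the injected current is the sum of three
#' components — Ornstein-Uhlenbeck noise mimicking ongoing synaptic
#' background, a train of artificial PSCs of fixed amplitude (the
#' "signal" whose transmission is studied), and a DC offset that sets the
#' firing rate.
#'
#' @param ou An [ou_spec()] for the background noise.
#' @param kernel A [psc_kernel()]; the signal-in-noise default in this
#'   package's configs is rise 1 ms, decay 10 ms.
#' @param amplitude Signal PSC peak amplitude, pA (positive for
#'   excitatory, negative for inhibitory).
#' @param onsets Signal PSC onset times, seconds.
#' @param dc DC offset, pA.
#' @param duration Trace length, seconds.
#' @param seed Optional integer seed for the noise.
#' @return List with `trace` (a [current_trace()]) and `triggers` (a
#'   trigger table, see [trigger_table()]).
#' @export
synthesize_signal_in_noise <- function(ou, kernel, amplitude, onsets,
                                       dc = 0, duration, seed = NULL) {
  noise <- generate_ou(ou, duration, seed = seed)
  sig <- render_psc_train(kernel, onsets, abs(amplitude), duration)
  sgn <- if (amplitude >= 0) "E" else "I"
  samples <- noise$samples + sign(amplitude) * sig$samples + dc
  trg <- trigger_table(
    neuron_id = rep.int(0L, length(onsets)),
    sign = rep.int(sgn, length(onsets)),
    amplitude_pA = rep.int(abs(amplitude), length(onsets)),
    amplitude_class = rep.int(1L, length(onsets)),
    onset_time_s = onsets)
  trace <- current_trace(samples, kernel$dt, dc = dc,
                         meta = list(paradigm = "signal_in_noise",
                                     amplitude = amplitude,
                                     sigma = ou$sigma, seed = seed))
  list(trace = trace, triggers = trg)
}

#' Trigger table constructor
#'
#' The ground-truth record of every artificial PSC in an injected
#' current: which model presynaptic neuron fired, the sign and amplitude
#' (class) of its PSC, and the onset time. One row per presynaptic spike.
#'
#' @param neuron_id Integer ids.
#' @param sign "E" or "I".
#' @param amplitude_pA Peak amplitude as injected (after any scaling), pA.
#' @param amplitude_class Discrete level index.
#' @param onset_time_s Onset time, seconds.
#' @return A `data.frame` with class `trigger_table`, ordered by onset.
#' @export
trigger_table <- function(neuron_id, sign, amplitude_pA, amplitude_class,
                          onset_time_s) {
  df <- data.frame(neuron_id = as.integer(neuron_id), sign = sign,
                   amplitude_pA = amplitude_pA,
                   amplitude_class = as.integer(amplitude_class),
                   onset_time_s = onset_time_s, stringsAsFactors = FALSE)
  df <- df[order(df$onset_time_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("trigger_table", "data.frame")
  df
}

#' Synthesize a fully-defined signal mixture current
#'
#' Second stimulation paradigm: the injected current is the summed PSC
#' activity of the whole model presynaptic population — excitatory PSCs
#' positive, inhibitory negative. Because the population is balanced the
#' sum fluctuates around zero; it is then rescaled globally so its SD
#' equals `target_sd` (emulating the experimental scaling of the current
#' until membrane-potential fluctuations reach 15-20 mV), and the DC
#' offset is added after scaling. The returned trigger table records
#' every presynaptic spike with its scaled amplitude, so any input can
#' later be treated as "signal" and all others as "noise".
#'
#' @param pop A [build_population()] result whose trains cover `duration`.
#' @param kernel A [psc_kernel()] (mixture default: rise 0.5 ms, decay 5 ms).
#' @param target_sd Target SD of the pre-DC current, pA. Default 100.
#' @param dc DC offset, pA. Default 0.
#' @param duration Trace length, seconds; defaults to the population's
#'   train duration.
#' @return List with `trace`, `triggers` and `scale_factor` (the
#'   dimensionless factor applied to the raw PSC sum; scaled amplitude in
#'   units of the current SD is `amplitude_pA * scale_factor / target_sd`).
#' @export
synthesize_mixture <- function(pop, kernel, target_sd = 100, dc = 0,
                               duration = NULL) {
  stopifnot(inherits(pop, "presyn_population"), inherits(kernel, "psc_kernel"))
  if (nrow(pop$roster) == 0) stop("population is empty")
  if (is.null(duration)) duration <- pop$renewal$duration
  n <- round(duration * 1000 / kernel$dt)
  n_spk <- lengths(pop$trains)
  onset <- unlist(pop$trains, use.names = FALSE)
  nid <- rep.int(pop$roster$neuron_id, n_spk)
  sgn <- rep.int(pop$roster$sign, n_spk)
  amp <- rep.int(pop$roster$amplitude_pA, n_spk)
  cls <- rep.int(pop$roster$amplitude_class, n_spk)
  keep <- onset <= duration
  onset <- onset[keep]; nid <- nid[keep]; sgn <- sgn[keep]
  amp <- amp[keep]; cls <- cls[keep]
  w <- ifelse(sgn == "E", amp, -amp)
  delta <- numeric(n)
  idx <- as.integer(round(onset * 1000 / kernel$dt)) + 1L
  ok <- idx >= 1L & idx <= n
  add <- rowsum(w[ok], idx[ok])
  delta[as.integer(rownames(add))] <- add[, 1L]
  raw <- render_deltas(delta, kernel)
  raw_sd <- stats::sd(raw)
  if (raw_sd == 0) stop("population produced a flat current; cannot scale")
  scale_factor <- target_sd / raw_sd
  samples <- raw * scale_factor + dc
  trg <- trigger_table(nid, sgn, amp * scale_factor, cls, onset)
  trace <- current_trace(samples, kernel$dt, dc = dc,
                         meta = list(paradigm = "mixture",
                                     target_sd = target_sd,
                                     scale_factor = scale_factor,
                                     seed = pop$seed))
  list(trace = trace, triggers = trg, scale_factor = scale_factor)
}
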