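#' Specification of a gamma renewal spike-train generator
#'
#' Presynaptic firing is modelled as a gamma renewal process: inter-spike
#' intervals (ISIs) are i.i.d. gamma draws with shape `shape` and scale
#' chosen so that the mean ISI equals `1/rate`. Intervals shorter than
#' `min_isi` are redrawn (rejection resampling) so that consecutive PSCs
#' from one input never overlap strongly.
#'
#' The process is parameterized by its mean rate; the equivalent gamma
#' scale in milliseconds, `(1000/rate)/shape`, is stored in `scale_ms`
#' for reference (100 ms at the defaults of shape 2 and 5 Hz).
#'
#' @param shape Gamma shape parameter k (dimensionless, > 0). Default 2,
#'   giving firing more regular than Poisson (ISI CV^2 = 1/2).
#' @param rate Target mean firing rate in Hz (> 0). Default 5.
#' @param min_isi Minimum allowed inter-spike interval in ms (>= 0);
#'   shorter draws are resampled. Default 10.
#' @param duration Train duration in seconds (>= 0). Default 46, the
#'   length of one current-injection episode.
#' @return An object of class `renewal_spec`.
#' @examples
#' spec <- renewal_spec()
#' spec$scale_ms  # 100 ms
#' @export
renewal_spec <- function(shape = 2, rate = 5, min_isi = 10, duration = 46) {
  if (!is.numeric(shape) || shape <= 0) stop("'shape' must be > 0")
  if (!is.numeric(rate) || rate <= 0) stop("'rate' must be > 0")
  if (!is.numeric(min_isi) || min_isi < 0) stop("'min_isi' must be >= 0")
  if (!is.numeric(duration) || duration < 0) stop("'duration' must be >= 0")
  structure(
    list(shape = shape, rate = rate, min_isi = min_isi, duration = duration,
         scale_ms = (1000 / rate) / shape),
    class = "renewal_spec")
}

#' @export
print.renewal_spec <- function(x, ...) {
  cat(sprintf(
    "Gamma renewal spec: shape %g, mean rate %g Hz (scale %g ms), min ISI %g ms, duration %g s\n",
    x$shape, x$rate, x$min_isi, x$scale_ms, x$duration))
  invisible(x)
}

# Draw n gamma ISIs (seconds), rejection-resampling any draw below the floor.
draw_isis <- function(n, spec) {
  scale_s <- 1 / (spec$rate * spec$shape)
  min_s <- spec$min_isi / 1000
  x <- stats::rgamma(n, shape = spec$shape, scale = scale_s)
  bad <- which(x < min_s)
  while (length(bad)) {
    x[bad] <- stats::rgamma(length(bad), shape = spec$shape, scale = scale_s)
    bad <- bad[x[bad] < min_s]
  }
  x
}

#' Sample one spike train from a gamma renewal process
#'
#' Generates spike times on `[0, duration]` by accumulating ISIs drawn
#' from the gamma renewal process described by `spec`, with the
#' minimum-interval resampling rule applied to every draw (including the
#' first interval: the process is an ordinary, not equilibrium, renewal
#' process started at time 0).
#'
#' @param spec A [renewal_spec()].
#' @param seed Optional integer seed; if supplied the train is a pure
#'   function of `(spec, seed)`.
#' @return Numeric vector of strictly increasing spike times in seconds,
#'   all within `[0, duration]`, with successive differences at least
#'   `min_isi`.
#' @examples
#' tr <- sample_renewal_train(renewal_spec(duration = 10), seed = 1)
#' min(diff(tr)) >= 0.010
#' @export
sample_renewal_train <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "renewal_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (spec$duration == 0) return(numeric(0))
  chunk <- ceiling(spec$duration * spec$rate * 1.25) + 25
  times <- cumsum(draw_isis(chunk, spec))
  while (times[length(times)] < spec$duration) {
    times <- c(times, times[length(times)] + cumsum(draw_isis(chunk, spec)))
  }
  times[times <= spec$duration]
}

#' Discretized log-normal PSC amplitude distribution
#'
#' PSC peak amplitudes follow a log-normal law, as observed for unitary
#' EPSP/EPSC amplitudes in paired cortical recordings, constrained to a
#' fixed set of log-spaced levels so that every amplitude defines a
#' discrete "amplitude class" whose detectability can be analyzed
#' separately.
#'
#' @param mu_log Mean of the natural log amplitude (log-pA). Default 0.702.
#' @param sigma_log SD of the natural log amplitude (> 0). Default 0.9355.
#' @param n_levels Number of discrete levels (>= 1). Default 32.
#' @param span_sd Half-width of the discretization range in units of
#'   `sigma_log` (log space). Default 3.5.
#' @return An object of class `amplitude_dist`.
#' @export
amplitude_dist <- function(mu_log = 0.702, sigma_log = 0.9355,
                           n_levels = 32, span_sd = 3.5) {
  if (!is.numeric(sigma_log) || sigma_log <= 0) stop("'sigma_log' must be > 0")
  if (!is.numeric(n_levels) || n_levels < 1 || n_levels != round(n_levels))
    stop("'n_levels' must be a positive integer")
  if (!is.numeric(span_sd) || span_sd <= 0) stop("'span_sd' must be > 0")
  structure(
    list(mu_log = mu_log, sigma_log = sigma_log,
         n_levels = as.integer(n_levels), span_sd = span_sd),
    class = "amplitude_dist")
}

#' Discretize a log-normal amplitude distribution onto log-spaced levels
#'
#' Places `n_levels` log-spaced levels centered (in log space) on
#' `mu_log`, spanning `mu_log +/- span_sd * sigma_log`. Each level's
#' probability is the log-normal mass of the bin delimited by the
#' midpoints between adjacent log-levels; the two tails are folded into
#' the edge bins, so probabilities sum to one exactly.
#'
#' @param dist An [amplitude_dist()].
#' @return List with `levels` (pA, strictly increasing) and `probs`
#'   (summing to 1).
#' @examples
#' d <- discretize_lognormal(amplitude_dist())
#' length(d$levels)  # 32
#' sum(d$probs)      # 1
#' @export
discretize_lognormal <- function(dist) {
  stopifnot(inherits(dist, "amplitude_dist"))
  n <- dist$n_levels
  if (n == 1L)
    return(list(levels = exp(dist$mu_log), probs = 1))
  lg <- seq(dist$mu_log - dist$span_sd * dist$sigma_log,
            dist$mu_log + dist$span_sd * dist$sigma_log,
            length.out = n)
  edges <- c(-Inf, (lg[-1] + lg[-n]) / 2, Inf)
  probs <- diff(stats::pnorm(edges, mean = dist$mu_log, sd = dist$sigma_log))
  probs <- probs / sum(probs)
  list(levels = exp(lg), probs = probs)
}

#' Sample PSC amplitudes from the discretized distribution
#'
#' @param dist An [amplitude_dist()].
#' @param n Number of amplitudes to draw.
#' @param seed Optional integer seed.
#' @param stratified If `TRUE`, amplitudes are assigned by largest-remainder
#'   apportionment of the level probabilities (each level receives close to
#'   its expected count) and then shuffled, instead of i.i.d. sampling.
#' @return List with `amplitude` (pA) and `class` (level index, 1-based).
#' @export
sample_amplitudes <- function(dist, n, seed = NULL, stratified = FALSE) {
  disc <- discretize_lognormal(dist)
  if (!is.null(seed)) set.seed(seed)
  if (stratified) {
    exp_n <- disc$probs * n
    cnt <- floor(exp_n)
    rem <- n - sum(cnt)
    if (rem > 0) {
      extra <- order(exp_n - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1
    }
    cls <- sample(rep.int(seq_along(disc$levels), cnt))
  } else {
    cls <- sample.int(length(disc$levels), n, replace = TRUE, prob = disc$probs)
  }
  list(amplitude = disc$levels[cls], class = cls)
}

# Derive reproducible per-stream child seeds from one master seed.
substream_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Build a defined presynaptic population
#'
#' Assembles the full roster of model input neurons: each neuron gets a
#' sign (excitatory or inhibitory), a PSC amplitude drawn from the
#' discretized log-normal distribution (E and I share the same
#' distribution, differing only by sign), and an independent gamma
#' renewal spike train. All randomness is derived from `seed` through
#' per-neuron substreams, so any neuron's train can be regenerated
#' individually and the whole population is reproducible.
#'
#' @param n_total Total number of presynaptic neurons. Default 1024.
#' @param e_fraction Fraction of excitatory neurons; `n_total * e_fraction`
#'   must be an integer. Default 0.5 (balanced input).
#' @param renewal A [renewal_spec()] shared by all neurons.
#' @param dist An [amplitude_dist()].
#' @param seed Master integer seed.
#' @param stratified Passed to [sample_amplitudes()]; applied within each
#'   sign group.
#' @return An object of class `presyn_population`: list with `roster`
#'   (data.frame: neuron_id, sign, amplitude_pA, amplitude_class),
#'   `trains` (list of spike-time vectors, seconds), and the generating
#'   `renewal`, `dist`, `seed`.
#' @examples
#' pop <- build_population(n_total = 8, renewal = renewal_spec(duration = 2),
#'                         seed = 1)
#' table(pop$roster$sign)
#' @export
build_population <- function(n_total = 1024, e_fraction = 0.5,
                             renewal = renewal_spec(),
                             dist = amplitude_dist(),
                             seed = 1L, stratified = FALSE) {
  n_e <- n_total * e_fraction
  if (abs(n_e - round(n_e)) > 1e-9)
    stop("'n_total * e_fraction' must be an integer neuron count")
  n_e <- as.integer(round(n_e))
  n_i <- n_total - n_e
  seeds <- substream_seeds(seed, n_total + 2L)
  amp_e <- sample_amplitudes(dist, n_e, seed = seeds[1L], stratified = stratified)
  amp_i <- sample_amplitudes(dist, n_i, seed = seeds[2L], stratified = stratified)
  roster <- data.frame(
    neuron_id = seq_len(n_total),
    sign = rep(c("E", "I"), c(n_e, n_i)),
    amplitude_pA = c(amp_e$amplitude, amp_i$amplitude),
    amplitude_class = c(amp_e$class, amp_i$class),
    stringsAsFactors = FALSE)
  trains <- lapply(seq_len(n_total), function(i)
    sample_renewal_train(renewal, seed = seeds[i + 2L]))
  structure(
    list(roster = roster, trains = trains, renewal = renewal, dist = dist,
         seed = seed),
    class = "presyn_population")
}

#' @export
print.presyn_population <- function(x, ...) {
  cat(sprintf(
    "Presynaptic population: %d neurons (%d E / %d I), %d amplitude classes, %g s trains\n",
    nrow(x$roster), sum(x$roster$sign == "E"), sum(x$roster$sign == "I"),
    length(unique(x$roster$amplitude_class)), x$renewal$duration))
  invisible(x)
}

#' Regenerate the population's spike trains from a new seed
#'
#' Keeps the roster (signs, amplitudes) fixed and draws a fresh
#' realization of every neuron's spike train — one episode's worth of
#' presynaptic activity. Used by [run_episodes()] so each injection
#' episode carries an independent realization of the same defined
#' population.
#'
#' @param pop A [build_population()] result.
#' @param seed Integer seed for this realization.
#' @param duration Optional train duration (s); defaults to the
#'   population's renewal spec duration.
#' @return A `presyn_population` with new `trains`.
#' @export
regenerate_trains <- function(pop, seed, duration = NULL) {
  stopifnot(inherits(pop, "presyn_population"))
  spec <- pop$renewal
  if (!is.null(duration))
    spec <- renewal_spec(spec$shape, spec$rate, spec$min_isi, duration)
  seeds <- substream_seeds(seed, nrow(pop$roster))
  pop$trains <- lapply(seq_len(nrow(pop$roster)), function(i)
    sample_renewal_train(spec, seed = seeds[i]))
  pop$renewal <- spec
  pop
}

#' Maximum-likelihood gamma fit to pooled inter-spike intervals
#'
#' Convenience wrapper around [MASS::fitdistr()] for checking the renewal
#' statistics of generated trains: pools the ISIs of all supplied trains
#' and fits a two-parameter gamma distribution by maximum likelihood.
#'
#' @param trains List of spike-time vectors (seconds), or a single vector.
#' @return Named vector with `shape`, `rate` (1/s) and `n` (ISIs used).
#' @export
fit_isi_gamma <- function(trains) {
  if (!is.list(trains)) trains <- list(trains)
  isi <- unlist(lapply(trains, diff), use.names = FALSE)
  isi <- isi[is.finite(isi) & isi > 0]
  if (length(isi) < 10) stop("too few ISIs for a gamma fit")
  m <- mean(isi); v <- stats::var(isi)
  fit <- MASS::fitdistr(isi, "gamma",
                        start = list(shape = m^2 / v, rate = m / v),
                        lower = c(1e-6, 1e-6))
  c(shape = unname(fit$estimate["shape"]),
    rate = unname(fit$estimate["rate"]),
    n = length(isi))
}
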