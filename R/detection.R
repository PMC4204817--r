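#' Collect onset-triggered sweeps from episodes
#'
#' Aligns postsynaptic spike times to the onset of every artificial PSC:
#' each trigger contributes one "sweep" holding the spike times relative
#' to that onset within `[-T_max, +T_max]` ms. Sweeps are grouped by
#' (sign, amplitude class). Triggers inside the discard window or closer
#' than `T_max` to an episode edge are excluded, so every sweep's pre-
#' and post-windows lie entirely inside the analyzed part of its episode.
#'
#' @param episodes An [run_episodes()] result, or an object assembled by
#'   [as_episode_set()] from externally recorded spikes and triggers.
#' @param T_max Half-width of the alignment window, ms. Default 15.
#' @param class_of Optional function mapping the trigger table's
#'   `amplitude_class` (and `amplitude_pA`) to a coarser grouping label,
#'   e.g. to pool neighbouring amplitude levels; called as
#'   `class_of(amplitude_class, amplitude_pA)`. Default: the amplitude
#'   class itself.
#' @return Object of class `triggered_sweeps`: list with `events`
#'   (data.frame: group, sign, sweep, rel_ms), `groups` (data.frame:
#'   group, sign, amplitude_pA mean, amplitude_sd units, n_sweeps) and
#'   `T_max`.
#' @export
collect_sweeps <- function(episodes, T_max = 15, class_of = NULL) {
  stopifnot(inherits(episodes, "episode_set"))
  T_max_s <- T_max / 1000
  ev_list <- list(); trg_list <- list()
  sweep_off <- 0L
  for (ep in episodes$episodes) {
    trg <- ep$triggers
    lo <- max(episodes$discard_s + T_max_s, T_max_s)
    keep <- trg$onset_time_s >= lo &
      trg$onset_time_s <= episodes$episode_s - T_max_s
    trg <- trg[keep, , drop = FALSE]
    if (!nrow(trg)) next
    spikes <- sort(ep$spike_times[ep$spike_times >= episodes$discard_s])
    i1 <- findInterval(trg$onset_time_s - T_max_s, spikes) + 1L
    i2 <- findInterval(trg$onset_time_s + T_max_s, spikes)
    cnt <- pmax(i2 - i1 + 1L, 0L)
    sweep_ids <- sweep_off + seq_len(nrow(trg))
    if (any(cnt > 0)) {
      has <- cnt > 0L
      sp_idx <- sequence(cnt[has], from = i1[has])
      rep_idx <- rep.int(which(has), cnt[has])
      ev_list[[length(ev_list) + 1L]] <- data.frame(
        grp_class = trg$amplitude_class[rep_idx],
        grp_amp = trg$amplitude_pA[rep_idx],
        sign = trg$sign[rep_idx],
        sweep = sweep_ids[rep_idx],
        rel_ms = (spikes[sp_idx] - trg$onset_time_s[rep_idx]) * 1000,
        stringsAsFactors = FALSE)
    }
    trg$sweep <- sweep_ids
    trg$sd_units <- trg$amplitude_pA / episodes$target_sd
    trg_list[[length(trg_list) + 1L]] <- trg
    sweep_off <- sweep_off + nrow(trg)
  }
  trg_all <- do.call(rbind, trg_list)
  if (is.null(trg_all) || !nrow(trg_all)) stop("no usable triggers")
  if (is.null(class_of)) class_of <- function(cls, amp) cls
  apply_class <- function(cls, amp)
    rep_len(class_of(cls, amp), length(cls))
  trg_all$group <- apply_class(trg_all$amplitude_class, trg_all$amplitude_pA)
  events <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(grp_class = integer(0), grp_amp = numeric(0),
               sign = character(0), sweep = integer(0), rel_ms = numeric(0))
  events$group <- apply_class(events$grp_class, events$grp_amp)
  key <- interaction(trg_all$sign, trg_all$group, drop = TRUE)
  groups <- data.frame(
    sign = tapply(trg_all$sign, key, `[`, 1),
    group = tapply(trg_all$group, key, `[`, 1),
    amplitude_pA = as.numeric(tapply(trg_all$amplitude_pA, key, mean)),
    amplitude_sd = as.numeric(tapply(trg_all$sd_units, key, mean)),
    n_sweeps = as.integer(table(key)),
    stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  groups <- groups[order(groups$sign, groups$amplitude_pA), , drop = FALSE]
  events <- events[, c("group", "sign", "sweep", "rel_ms")]
  structure(list(events = events, groups = groups, T_max = T_max),
            class = "triggered_sweeps")
}

#' @export
print.triggered_sweeps <- function(x, ...) {
  cat(sprintf(
    "Triggered sweeps: %d groups, %d sweeps total, %d aligned spikes, window +/- %g ms\n",
    nrow(x$groups), sum(x$groups$n_sweeps), nrow(x$events), x$T_max))
  invisible(x)
}

#' Assemble an episode set from external spike and trigger tables
#'
#' Lets the analysis half run on real recordings: supply postsynaptic
#' spike times and the trigger table (e.g. read with
#' [read_spikes_csv()] / [read_triggers_csv()]) and get an object that
#' [collect_sweeps()] accepts.
#'
#' @param spikes data.frame with columns `episode_id`, `time_s`.
#' @param triggers data.frame with trigger-table columns plus
#'   `episode_id` (a [trigger_table()] per episode after splitting).
#' @param episode_s Episode duration, s.
#' @param discard_s Discard window, s. Default 2.
#' @param target_sd Current SD used in the experiment, pA (for amplitude
#'   reporting in SD units). Default 100.
#' @return An `episode_set`.
#' @export
as_episode_set <- function(spikes, triggers, episode_s, discard_s = 2,
                           target_sd = 100) {
  ids <- sort(unique(c(spikes$episode_id, triggers$episode_id)))
  eps <- lapply(ids, function(id) {
    trg <- triggers[triggers$episode_id == id, , drop = FALSE]
    list(spike_times = sort(spikes$time_s[spikes$episode_id == id]),
         triggers = trigger_table(trg$neuron_id, trg$sign, trg$amplitude_pA,
                                  trg$amplitude_class, trg$onset_time_s),
         scale_factor = NA_real_,
         rate = NA_real_)
  })
  structure(list(episodes = eps, episode_s = episode_s,
                 discard_s = discard_s, dc = NA_real_,
                 target_sd = target_sd, params = NULL, seed = NA),
            class = "episode_set")
}

#' Onset-triggered peri-stimulus time histogram
#'
#' Firing rate of the model population as a function of time relative to
#' PSC onset, computed per (sign, group): bin counts divided by
#' `n_sweeps * bin width`, in Hz.
#'
#' @param sweeps A [collect_sweeps()] result.
#' @param bin Bin width, ms. Default 0.5.
#' @return data.frame with columns `sign`, `group`, `t_ms` (bin centre),
#'   `rate_hz`, `count`, `n_sweeps`.
#' @export
build_psth <- function(sweeps, bin = 0.5) {
  stopifnot(inherits(sweeps, "triggered_sweeps"), bin > 0)
  breaks <- seq(-sweeps$T_max, sweeps$T_max, by = bin)
  centres <- (breaks[-1] + breaks[-length(breaks)]) / 2
  out <- lapply(seq_len(nrow(sweeps$groups)), function(i) {
    g <- sweeps$groups[i, ]
    ev <- sweeps$events[sweeps$events$group == g$group &
                          sweeps$events$sign == g$sign, ]
    cnt <- hist(ev$rel_ms[ev$rel_ms >= breaks[1] &
                            ev$rel_ms < breaks[length(breaks)]],
                breaks = breaks, plot = FALSE)$counts
    data.frame(sign = g$sign, group = g$group, t_ms = centres,
               rate_hz = cnt / (g$n_sweeps * bin / 1000), count = cnt,
               n_sweeps = g$n_sweeps, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pre- and post-onset window spike probabilities
#'
#' For each (sign, group) and a window length `T`, estimates the
#' probability of at least one postsynaptic spike in the window `[-T, 0)`
#' ms before PSC onset (`P_pre`) and `[0, T)` ms after (`P_post`), as the
#' fraction of sweeps containing a spike. The spike-count based estimate
#' (total spikes / sweeps) is also returned: at these firing rates and
#' window lengths sweeps contain at most one spike, so the two coincide;
#' their difference is reported so the assumption can be checked.
#'
#' @param sweeps A [collect_sweeps()] result.
#' @param T Window length, ms (must be <= `T_max`).
#' @return data.frame with `sign`, `group`, `amplitude_pA`,
#'   `amplitude_sd`, `T_ms`, `P_pre`, `P_post`, `P_pre_count`,
#'   `P_post_count`, `n_sweeps`.
#' @export
window_probs <- function(sweeps, T) {
  stopifnot(inherits(sweeps, "triggered_sweeps"))
  if (T > sweeps$T_max) stop("'T' exceeds the collected window T_max")
  g <- sweeps$groups
  if (any(g$n_sweeps == 0)) stop("group with zero sweeps")
  ev <- sweeps$events
  key_g <- paste(g$sign, g$group, sep = "\r")
  stat <- function(sel) {
    sub <- ev[sel, ]
    key <- paste(sub$sign, sub$group, sep = "\r")
    n_spk <- tapply(sub$rel_ms, key, length)
    n_swp <- tapply(sub$sweep, key, function(s) length(unique(s)))
    cnt <- ind <- numeric(nrow(g))
    m <- match(names(n_spk), key_g)
    cnt[m] <- as.numeric(n_spk); ind[m] <- as.numeric(n_swp)
    list(ind = ind / g$n_sweeps, cnt = cnt / g$n_sweeps)
  }
  post <- stat(ev$rel_ms >= 0 & ev$rel_ms < T)
  pre <- stat(ev$rel_ms >= -T & ev$rel_ms < 0)
  data.frame(sign = g$sign, group = g$group, amplitude_pA = g$amplitude_pA,
             amplitude_sd = g$amplitude_sd, T_ms = T,
             P_pre = pre$ind, P_post = post$ind,
             P_pre_count = pre$cnt, P_post_count = post$cnt,
             n_sweeps = g$n_sweeps, stringsAsFactors = FALSE)
}

#' Parametric (binomial) detection probability
#'
#' Models the population spike counts in the pre- and post-onset windows
#' as independent binomial variables `B(N, P_pre)` and `B(N, P_post)`
#' over `N` transmitting neurons. An excitatory input is detected when
#' the post-onset count exceeds the `1 - alpha` quantile of the
#' pre-signal distribution; an inhibitory input when the count falls
#' below the `alpha` quantile. With the quantile defined as the smallest
#' k whose CDF reaches the target probability and strict exceedance,
#' detection probability at `P_post = P_pre` never exceeds `alpha`
#' (decoder false-positive calibration).
#'
#' All arguments are vectorized.
#'
#' @param p_pre,p_post Per-sweep spike probabilities in `[0, 1]`.
#' @param n Population size (number of sweeps summed by the decoder).
#' @param sign "E" or "I".
#' @param alpha Decoder tail probability. Default 0.05.
#' @return Detection probability in `[0, 1]`.
#' @examples
#' parametric_detection(0.001, 0.003, 1000, "E")  # ~0.35
#' @export
parametric_detection <- function(p_pre, p_post, n, sign = "E", alpha = 0.05) {
  k <- max(length(p_pre), length(p_post), length(n), length(sign))
  p_pre <- rep_len(p_pre, k); p_post <- rep_len(p_post, k)
  n <- rep_len(n, k); sign <- rep_len(sign, k)
  stopifnot(all(p_pre >= 0 & p_pre <= 1), all(p_post >= 0 & p_post <= 1),
            all(n >= 1), all(sign %in% c("E", "I")))
  out <- numeric(k)
  e <- sign == "E"
  if (any(e)) {
    q <- stats::qbinom(1 - alpha, n[e], p_pre[e])
    out[e] <- stats::pbinom(q, n[e], p_post[e], lower.tail = FALSE)
  }
  if (any(!e)) {
    q <- stats::qbinom(alpha, n[!e], p_pre[!e])
    out[!e] <- stats::pbinom(q - 1, n[!e], p_post[!e])
  }
  out
}

# Per-sweep spike counts in the pre/post windows for one (sign, group).
sweep_window_counts <- function(sweeps, T, sign, group) {
  g <- sweeps$groups
  row <- which(g$sign == sign & g$group == group)
  if (!length(row)) stop("no such (sign, group) in sweeps")
  n_sw <- g$n_sweeps[row]
  ev <- sweeps$events[sweeps$events$sign == sign &
                        sweeps$events$group == group, ]
  # sweep ids are global; map to 1..n_sw within the group
  ids <- sort(unique(ev$sweep))
  pre <- post <- integer(n_sw)
  sel_post <- ev$rel_ms >= 0 & ev$rel_ms < T
  sel_pre <- ev$rel_ms >= -T & ev$rel_ms < 0
  if (any(sel_post)) {
    t <- table(match(ev$sweep[sel_post], ids))
    post[as.integer(names(t))] <- as.integer(t)
  }
  if (any(sel_pre)) {
    t <- table(match(ev$sweep[sel_pre], ids))
    pre[as.integer(names(t))] <- as.integer(t)
  }
  # sweeps with no aligned spikes at all keep their implicit zero counts
  list(pre = pre, post = post, n_sweeps = n_sw)
}

# Empirical type-1 quantile: smallest value whose ECDF reaches p.
quantile_type1 <- function(x, p) {
  sort(x)[pmin(pmax(ceiling(p * length(x)), 1L), length(x))]
}

#' Bootstrap detection probability
#'
#' Nonparametric counterpart of [parametric_detection()]. Per
#' repetition: `n_sets` trial sets of `N` sweeps are drawn (with
#' replacement by default) from the group's sweeps; the distribution of
#' summed pre-onset spike counts over all trial sets defines the
#' pre-signal distribution, whose `1 - alpha` (excitatory) or `alpha`
#' (inhibitory) empirical quantile is the decoder threshold; the
#' fraction of trial sets whose summed post-onset count falls strictly
#' above (E) or below (I) the threshold is one detection estimate. The
#' mean and SD over `n_reps` repetitions are returned.
#'
#' @param sweeps A [collect_sweeps()] result.
#' @param T Window length, ms.
#' @param N Population size (sweeps per trial set).
#' @param sign,group Which (sign, amplitude group) to analyze.
#' @param n_sets Trial sets per repetition. Default 100.
#' @param n_reps Repetitions. Default 100.
#' @param alpha Decoder tail probability. Default 0.05.
#' @param seed Optional integer seed.
#' @param replace Resample with replacement. Default TRUE; with
#'   `replace = FALSE` the group must hold at least `n_sets * N` sweeps.
#' @param pre_quantile "pooled" (default): threshold from the pooled
#'   pre-count distribution over all trial sets of the repetition;
#'   "per_set": each trial set is tested against the binomial quantile
#'   implied by its own mean pre-window spike probability.
#' @return Named vector: `detection` (mean over repetitions),
#'   `dispersion` (SD over repetitions).
#' @export
bootstrap_detection <- function(sweeps, T, N, sign, group,
                                n_sets = 100, n_reps = 100, alpha = 0.05,
                                seed = NULL, replace = TRUE,
                                pre_quantile = c("pooled", "per_set")) {
  pre_quantile <- match.arg(pre_quantile)
  cc <- sweep_window_counts(sweeps, T, sign, group)
  if (!replace && cc$n_sweeps < n_sets * N)
    stop("not enough sweeps to resample without replacement")
  if (!is.null(seed)) set.seed(seed)
  det <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    idx <- if (replace) sample.int(cc$n_sweeps, n_sets * N, replace = TRUE)
    else sample.int(cc$n_sweeps, n_sets * N)
    set_pre <- .colSums(cc$pre[idx], N, n_sets)
    set_post <- .colSums(cc$post[idx], N, n_sets)
    if (pre_quantile == "pooled") {
      if (sign == "E") {
        q <- quantile_type1(set_pre, 1 - alpha)
        det[r] <- mean(set_post > q)
      } else {
        q <- quantile_type1(set_pre, alpha)
        det[r] <- mean(set_post < q)
      }
    } else {
      p_hat <- set_pre / N
      if (sign == "E") {
        q <- stats::qbinom(1 - alpha, N, p_hat)
        det[r] <- mean(set_post > q)
      } else {
        q <- stats::qbinom(alpha, N, p_hat)
        det[r] <- mean(set_post < q)
      }
    }
  }
  c(detection = mean(det), dispersion = stats::sd(det))
}

#' Detection-probability surface
#'
#' Evaluates the decoder over a grid of integration windows `T_grid` and
#' population sizes `N_list` for every (sign, amplitude group) in the
#' sweeps, by the parametric binomial formula and/or the bootstrap.
#'
#' @param sweeps A [collect_sweeps()] result.
#' @param T_grid Integration windows, ms. Default `seq(0.4, 15, by = 0.4)`.
#' @param N_list Population sizes. Default `c(250, 500, 1000, 2000)`.
#' @param method "parametric", "bootstrap" or "both".
#' @param alpha Decoder tail probability. Default 0.05.
#' @param n_sets,n_reps Bootstrap sizes. Default 100 each.
#' @param seed Seed for the bootstrap.
#' @param rate_hz Optional firing-rate label carried into the output.
#' @return Tidy data.frame: `sign`, `group`, `amplitude_pA`,
#'   `amplitude_sd`, `T_ms`, `N`, `rate_hz`, `method`, `detection`,
#'   `dispersion` (NA for parametric).
#' @export
detection_surface <- function(sweeps, T_grid = seq(0.4, 15, by = 0.4),
                              N_list = c(250, 500, 1000, 2000),
                              method = c("parametric", "bootstrap", "both"),
                              alpha = 0.05, n_sets = 100, n_reps = 100,
                              seed = NULL, rate_hz = NA_real_) {
  method <- match.arg(method)
  stopifnot(length(T_grid) > 0, length(N_list) > 0)
  out <- list()
  if (method %in% c("parametric", "both")) {
    for (T in T_grid) {
      wp <- window_probs(sweeps, T)
      for (N in N_list) {
        det <- parametric_detection(wp$P_pre, wp$P_post, N, wp$sign, alpha)
        out[[length(out) + 1L]] <- data.frame(
          sign = wp$sign, group = wp$group, amplitude_pA = wp$amplitude_pA,
          amplitude_sd = wp$amplitude_sd, T_ms = T, N = N, rate_hz = rate_hz,
          method = "parametric", detection = det, dispersion = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (method %in% c("bootstrap", "both")) {
    if (!is.null(seed)) set.seed(seed)
    bseeds <- sample.int(.Machine$integer.max - 1L,
                         nrow(sweeps$groups) * length(T_grid) * length(N_list))
    i <- 0L
    for (gi in seq_len(nrow(sweeps$groups))) {
      g <- sweeps$groups[gi, ]
      for (T in T_grid) for (N in N_list) {
        i <- i + 1L
        b <- bootstrap_detection(sweeps, T, N, g$sign, g$group,
                                 n_sets = n_sets, n_reps = n_reps,
                                 alpha = alpha, seed = bseeds[i])
        out[[length(out) + 1L]] <- data.frame(
          sign = g$sign, group = g$group, amplitude_pA = g$amplitude_pA,
          amplitude_sd = g$amplitude_sd, T_ms = T, N = N, rate_hz = rate_hz,
          method = "bootstrap", detection = b[["detection"]],
          dispersion = b[["dispersion"]], stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Circularly shift trigger times (null control)
#'
#' Destroys the temporal relation between PSC onsets and postsynaptic
#' spikes while preserving both marginal statistics: each episode's
#' trigger times are shifted by a random offset, circularly within the
#' analyzed window `[discard_s, episode_s]`. With shifted triggers the
#' decoder should detect nothing above its nominal false-positive rate.
#'
#' @param episodes An `episode_set`.
#' @param seed Integer seed for the per-episode offsets.
#' @return An `episode_set` with shifted trigger tables.
#' @export
shift_triggers <- function(episodes, seed = 1L) {
  stopifnot(inherits(episodes, "episode_set"))
  set.seed(seed)
  span <- episodes$episode_s - episodes$discard_s
  offs <- stats::runif(length(episodes$episodes), min = 0.1 * span,
                       max = 0.9 * span)
  for (i in seq_along(episodes$episodes)) {
    trg <- episodes$episodes[[i]]$triggers
    t0 <- trg$onset_time_s - episodes$discard_s
    t0 <- (t0 + offs[i]) %% span
    trg$onset_time_s <- t0 + episodes$discard_s
    episodes$episodes[[i]]$triggers <-
      trigger_table(trg$neuron_id, trg$sign, trg$amplitude_pA,
                    trg$amplitude_class, trg$onset_time_s)
  }
  episodes
}
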