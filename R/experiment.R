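#' Default run configuration
#'
#' Returns the shipped default configuration of a fully-defined
#' signal-mixture experiment as a nested list: a population of 1024
#' presynaptic neurons (512 E / 512 I), gamma-renewal firing at 5 Hz
#' with shape 2 and a 10 ms interval floor, 32 log-spaced amplitude
#' levels from the log-normal law (mu 0.702, sigma 0.9355), PSC kernel
#' with 0.5 / 5 ms time constants on a 0.05 ms grid, current scaled to
#' SD 100 pA, 46 s episodes with a 2 s discard window, and the decoder
#' grid (T from 0.4 to 15 ms, N in 250/500/1000/2000).
#'
#' @param paradigm "mixture" (default) or "signal_in_noise".
#' @return Nested configuration list (see the shipped
#'   `inst/extdata/example-config.yaml` for the same content as YAML).
#' @export
default_config <- function(paradigm = c("mixture", "signal_in_noise")) {
  paradigm <- match.arg(paradigm)
  cfg <- list(
    paradigm = paradigm,
    seed = 1L,
    population = list(n_total = 1024L, e_fraction = 0.5),
    renewal = list(shape = 2, rate = 5, min_isi = 10),
    amplitude = list(mu_log = 0.702, sigma_log = 0.9355, n_levels = 32L,
                     span_sd = 3.5),
    kernel = list(tau_rise = 0.5, tau_decay = 5, dt = 0.05),
    current = list(target_sd = 100, dc = NULL),
    episodes = list(n = 31L, duration_s = 46, discard_s = 2),
    neuron = list(tau_m = 20, r_in = 140, v_rest = -70, v_thresh = -50,
                  v_reset = -60, t_ref = 3, target_rate = 5),
    analysis = list(T_grid = seq(0.4, 15, by = 0.4),
                    N_list = c(250L, 500L, 1000L, 2000L),
                    method = "parametric", alpha = 0.05,
                    n_sets = 100L, n_reps = 100L))
  if (paradigm == "signal_in_noise") {
    cfg$kernel <- list(tau_rise = 1, tau_decay = 10, dt = 0.05)
    cfg$signal <- list(amplitude = 50)
    cfg$noise <- list(sigma = 110, tau_corr = 5)
  }
  cfg
}

#' Read and validate a run configuration from YAML
#'
#' Missing fields are filled from [default_config()] for the file's
#' paradigm; unknown top-level fields raise an error.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config(user$paradigm %||% "mixture")
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  merge2 <- function(b, u) {
    if (!is.list(b) || !is.list(u)) return(u)
    for (nm in names(u)) b[[nm]] <- merge2(b[[nm]], u[[nm]])
    b
  }
  cfg <- merge2(base, user)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$paradigm %in% c("mixture", "signal_in_noise"))
  renewal_spec(cfg$renewal$shape, cfg$renewal$rate, cfg$renewal$min_isi,
               cfg$episodes$duration_s)
  amplitude_dist(cfg$amplitude$mu_log, cfg$amplitude$sigma_log,
                 cfg$amplitude$n_levels, cfg$amplitude$span_sd)
  psc_kernel(cfg$kernel$tau_rise, cfg$kernel$tau_decay, cfg$kernel$dt)
  stopifnot(cfg$episodes$n >= 1,
            cfg$episodes$duration_s > cfg$episodes$discard_s,
            cfg$current$target_sd > 0)
  invisible(cfg)
}

#' Run a complete experiment from a configuration
#'
#' End-to-end driver: builds the presynaptic population (mixture
#' paradigm) or the signal train (signal-in-noise paradigm), calibrates
#' the DC current to the target firing rate on a probe episode,
#' simulates all injection episodes with the model neuron, collects
#' onset-triggered sweeps, and evaluates the detection surface. When
#' `out_dir` is given, all intermediates (spikes, triggers, surface,
#' config echo with seeds) are written there so the analysis can be
#' re-run without re-simulation.
#'
#' @param config Configuration list ([default_config()] or
#'   [read_config()]).
#' @param out_dir Optional output directory for the artifact bundle.
#' @param n_episodes Optional override of `config$episodes$n` (for quick
#'   runs).
#' @return List with `config` (including the calibrated `dc` and
#'   achieved rate), `episodes` (an `episode_set`), `sweeps`, `psth` and
#'   `surface`.
#' @export
run_experiment <- function(config = default_config(), out_dir = NULL,
                           n_episodes = NULL) {
  validate_config(config)
  if (!is.null(n_episodes)) config$episodes$n <- n_episodes
  seeds <- substream_seeds(config$seed, 4L)
  kern <- psc_kernel(config$kernel$tau_rise, config$kernel$tau_decay,
                     config$kernel$dt)
  np <- neuron_params(config$neuron$tau_m, config$neuron$r_in,
                      config$neuron$v_rest, config$neuron$v_thresh,
                      config$neuron$v_reset, config$neuron$t_ref)
  dur <- config$episodes$duration_s

  if (config$paradigm == "mixture") {
    pop <- build_population(
      config$population$n_total, config$population$e_fraction,
      renewal_spec(config$renewal$shape, config$renewal$rate,
                   config$renewal$min_isi, dur),
      amplitude_dist(config$amplitude$mu_log, config$amplitude$sigma_log,
                     config$amplitude$n_levels, config$amplitude$span_sd),
      seed = seeds[1])
    dc <- config$current$dc
    achieved <- NA_real_
    if (is.null(dc)) {
      probe_pop <- regenerate_trains(pop, seeds[2], duration = dur)
      probe <- synthesize_mixture(probe_pop, kern,
                                  target_sd = config$current$target_sd,
                                  duration = dur)
      cal <- calibrate_dc(np, probe$trace, config$neuron$target_rate,
                          discard = config$episodes$discard_s)
      dc <- cal$dc; achieved <- cal$achieved_rate
    }
    eps <- run_episodes(np, pop, kern, config$episodes$n, dc,
                        episode_s = dur,
                        discard_s = config$episodes$discard_s,
                        target_sd = config$current$target_sd,
                        seed = seeds[3])
  } else {
    sig_spec <- renewal_spec(config$renewal$shape, config$renewal$rate,
                             config$renewal$min_isi, dur)
    ou <- ou_spec(config$noise$sigma, config$noise$tau_corr, config$kernel$dt)
    dc <- config$current$dc
    achieved <- NA_real_
    if (is.null(dc)) {
      probe <- generate_ou(ou, dur, seed = seeds[2])
      cal <- calibrate_dc(np, probe, config$neuron$target_rate,
                          discard = config$episodes$discard_s)
      dc <- cal$dc; achieved <- cal$achieved_rate
    }
    eseeds <- substream_seeds(seeds[3], config$episodes$n)
    episodes <- lapply(seq_len(config$episodes$n), function(e) {
      onsets <- sample_renewal_train(sig_spec, seed = eseeds[e])
      syn <- synthesize_signal_in_noise(ou, kern, config$signal$amplitude,
                                        onsets, dc = dc, duration = dur,
                                        seed = eseeds[e] + 1L)
      sim <- simulate_neuron(np, syn$trace)
      spikes <- detect_spikes(sim$voltage, sim$dt)
      list(spike_times = spikes, triggers = syn$triggers, scale_factor = 1,
           rate = measured_rate(spikes, dur, config$episodes$discard_s),
           rate_bins_5s = as.numeric(table(cut(spikes, seq(0, dur, by = 5)))) / 5,
           seed = eseeds[e])
    })
    eps <- structure(
      list(episodes = episodes, episode_s = dur,
           discard_s = config$episodes$discard_s, dc = dc,
           target_sd = config$noise$sigma, params = np, seed = seeds[3]),
      class = "episode_set")
  }

  sweeps <- collect_sweeps(eps, T_max = max(config$analysis$T_grid))
  psth <- build_psth(sweeps)
  surface <- detection_surface(
    sweeps, config$analysis$T_grid, config$analysis$N_list,
    method = config$analysis$method, alpha = config$analysis$alpha,
    n_sets = config$analysis$n_sets, n_reps = config$analysis$n_reps,
    seed = seeds[4],
    rate_hz = mean(vapply(eps$episodes, `[[`, numeric(1), "rate")))
  config$current$dc <- dc
  config$achieved_rate <- achieved

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_spikes_csv(eps, file.path(out_dir, "spikes.csv"))
    trg <- do.call(rbind, lapply(seq_along(eps$episodes), function(i)
      cbind(episode_id = i, as.data.frame(eps$episodes[[i]]$triggers))))
    utils::write.csv(trg, file.path(out_dir, "triggers.csv"),
                     row.names = FALSE)
    write_surface_csv(surface, file.path(out_dir, "detection_surface.csv"))
    utils::write.csv(psth, file.path(out_dir, "psth.csv"), row.names = FALSE)
    jsonlite::write_json(config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(config = config, episodes = eps, sweeps = sweeps, psth = psth,
       surface = surface)
}
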