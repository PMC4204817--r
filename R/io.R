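#' Write a current trace as single-column CSV
#'
#' Units are declared in a comment header line. Companion metadata
#' (dt, units, provenance) goes to a JSON sidecar `<path>.json`.
#'
#' @param trace A [current_trace()].
#' @param path Output file path.
#' @param sidecar Write the JSON sidecar. Default TRUE.
#' @export
write_trace_csv <- function(trace, path, sidecar = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# current_pA at dt = %g ms", trace$dt), con)
  writeLines("current_pA", con)
  writeLines(format(trace$samples, trim = TRUE, scientific = FALSE), con)
  if (sidecar) write_trace_sidecar(trace, paste0(path, ".json"))
  invisible(path)
}

write_trace_sidecar <- function(trace, path) {
  jsonlite::write_json(
    c(list(dt_ms = trace$dt, units = "pA", n_samples = length(trace$samples),
           dc_pA = trace$dc), trace$meta),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a current trace as raw little-endian float32 binary
#'
#' One 32-bit IEEE float per sample, little endian, no header; all
#' metadata (dt, units, seed, scale factor) goes to the JSON sidecar
#' `<path>.json`.
#'
#' @param trace A [current_trace()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trace_raw <- function(trace, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(trace$samples), con, size = 4L, endian = "little")
  write_trace_sidecar(trace, paste0(path, ".json"))
  invisible(path)
}

#' Read a raw float32 current trace written by [write_trace_raw()]
#' @param path File path (sidecar `<path>.json` must exist).
#' @return A [current_trace()].
#' @export
read_trace_raw <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- meta$n_samples
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  current_trace(x, meta$dt_ms, dc = meta$dc_pA %||% 0,
                meta = meta[setdiff(names(meta),
                                    c("dt_ms", "units", "n_samples", "dc_pA"))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a current trace as an Axon Text File (ATF)
#'
#' Writes a minimal ATF 1.0 file (time in seconds and current in pA)
#' that acquisition software such as pCLAMP can use as a stimulus
#' waveform.
#'
#' @param trace A [current_trace()].
#' @param path Output file path (conventionally `.atf`).
#' @export
write_trace_atf <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  header <- c(
    "ATF\t1.0",
    "2\t2",
    sprintf("\"AcquisitionMode=Episodic Stimulation\""),
    sprintf("\"SampleInterval=%g ms\"", trace$dt),
    "\"Time (s)\"\t\"Current (pA)\"")
  writeLines(header, con)
  t_s <- (seq_along(trace$samples) - 1L) * trace$dt / 1000
  writeLines(paste(format(t_s, trim = TRUE, scientific = FALSE),
                   format(trace$samples, trim = TRUE, scientific = FALSE),
                   sep = "\t"), con)
  invisible(path)
}

#' Write a population roster and its spike trains to CSV
#'
#' Roster columns: `neuron_id`, `sign`, `amplitude_pA`,
#' `amplitude_class`; spikes columns: `neuron_id`, `time_s`. A JSON
#' sidecar `<prefix>_config.json` records the renewal spec, amplitude
#' distribution and seed.
#'
#' @param pop A [build_population()] result.
#' @param prefix Path prefix; writes `<prefix>_roster.csv`,
#'   `<prefix>_spikes.csv`, `<prefix>_config.json`.
#' @return The three paths, invisibly.
#' @export
write_population_csv <- function(pop, prefix) {
  stopifnot(inherits(pop, "presyn_population"))
  roster_path <- paste0(prefix, "_roster.csv")
  spikes_path <- paste0(prefix, "_spikes.csv")
  cfg_path <- paste0(prefix, "_config.json")
  utils::write.csv(pop$roster, roster_path, row.names = FALSE)
  spikes <- data.frame(
    neuron_id = rep.int(pop$roster$neuron_id, lengths(pop$trains)),
    time_s = unlist(pop$trains, use.names = FALSE))
  utils::write.csv(spikes, spikes_path, row.names = FALSE)
  jsonlite::write_json(
    list(renewal = unclass(pop$renewal), amplitude = unclass(pop$dist),
         seed = pop$seed),
    cfg_path, auto_unbox = TRUE, digits = NA)
  invisible(c(roster_path, spikes_path, cfg_path))
}

#' Write a trigger table to CSV
#' @param triggers A [trigger_table()].
#' @param path Output path.
#' @export
write_triggers_csv <- function(triggers, path) {
  utils::write.csv(as.data.frame(triggers), path, row.names = FALSE)
  invisible(path)
}

#' Read a trigger table CSV
#'
#' Expects columns `neuron_id`, `sign`, `amplitude_pA`,
#' `amplitude_class`, `onset_time_s`, optionally `episode_id`.
#' @param path CSV path.
#' @return data.frame (with `episode_id` preserved if present).
#' @export
read_triggers_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read postsynaptic spike times
#'
#' Columns `episode_id`, `time_s` (seconds from episode start).
#' @param episodes An `episode_set` (for writing).
#' @param path CSV path.
#' @return `write_spikes_csv`: the path; `read_spikes_csv`: a data.frame.
#' @export
write_spikes_csv <- function(episodes, path) {
  stopifnot(inherits(episodes, "episode_set"))
  df <- do.call(rbind, lapply(seq_along(episodes$episodes), function(i)
    data.frame(episode_id = i,
               time_s = episodes$episodes[[i]]$spike_times)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a detection surface to tidy CSV
#' @param surface A [detection_surface()] result.
#' @param path CSV path.
#' @export
write_surface_csv <- function(surface, path) {
  utils::write.csv(surface, path, row.names = FALSE)
  invisible(path)
}
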