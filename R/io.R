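## Trial-table CSV schema: fixed leading column order, extra derived
## columns (alpha summaries, ground truth, kept flags) appended after.
TRIAL_COLUMNS <- c("session_id", "participant_id", "condition_order",
                   "light_condition", "trial_number", "delay_s",
                   "quadrant", "hemifield", "vertical_field",
                   "direction", "responded", "rt_ms")

#' Write / read a trial table CSV
#'
#' The canonical column order is `session_id, participant_id,
#' condition_order, light_condition, trial_number, delay_s, quadrant,
#' hemifield, vertical_field, direction, responded, rt_ms`; any derived
#' columns follow.
#'
#' @param trials data.frame of trials.
#' @param path output CSV path.
#' @return `writeTrialTable` returns `path` invisibly;
#'   `readTrialTable` returns the data.frame.
#' @export
writeTrialTable <- function(trials, path) {
  lead <- intersect(TRIAL_COLUMNS, names(trials))
  rest <- setdiff(names(trials), lead)
  write.csv(trials[, c(lead, rest), drop = FALSE], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrialTable
#' @export
readTrialTable <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read an EpochSet container
#'
#' On-disk layout: a directory holding `manifest.json` (n_trials,
#' n_channels, n_samples, fs_hz, t_start_ms, channel_labels, units,
#' dtype, byte_order, layout) and `data.bin` with 32-bit little-endian
#' floats in trial-major `[trial][channel][sample]` order.
#'
#' @param epochs an [EpochSet-class].
#' @param dir directory to create/use.
#' @param extra named list merged into the manifest (e.g. a config
#'   hash).
#' @return `writeEpochSet` returns `dir` invisibly; `readEpochSet`
#'   returns an [EpochSet-class].
#' @export
writeEpochSet <- function(epochs, dir, extra = list()) {
  stopifnot(is(epochs, "EpochSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- c(list(
    n_trials = nTrials(epochs), n_channels = nChannels(epochs),
    n_samples = nSamples(epochs), fs_hz = epochs@fs,
    t_start_ms = epochs@tStartMs,
    channel_labels = epochs@channelLabels,
    baseline_window_ms = epochs@baselineWindowMs,
    units = "uV", dtype = "float32", byte_order = "little",
    layout = "trial_channel_sample"), extra)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  ## [trial][channel][sample] major order: sample fastest on disk
  con <- file(file.path(dir, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(epochs@voltages, c(3L, 2L, 1L))), con,
           size = 4L, endian = "little")
  invisible(dir)
}

#' @rdname writeEpochSet
#' @export
readEpochSet <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  n <- man$n_trials * man$n_channels * man$n_samples
  con <- file(file.path(dir, "data.bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  arr <- aperm(array(x, c(man$n_samples, man$n_channels, man$n_trials)),
               c(3L, 2L, 1L))
  epochSet(arr, fs = man$fs_hz, tStartMs = man$t_start_ms,
           channelLabels = man$channel_labels,
           baselineWindowMs = as.numeric(man$baseline_window_ms %||%
                                           numeric(0)))
}

#' Write / read an AlphaSeries container
#'
#' Same manifest + binary layout as [writeEpochSet()], with
#' `grid_times_ms` and `band_hz` in the manifest.
#'
#' @param series an [AlphaSeries-class].
#' @param dir directory to create/use.
#' @param extra named list merged into the manifest.
#' @export
writeAlphaSeries <- function(series, dir, extra = list()) {
  stopifnot(is(series, "AlphaSeries"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(series@values)
  man <- c(list(
    n_trials = d[1L], n_channels = d[2L], n_samples = d[3L],
    grid_times_ms = series@gridTimesMs, band_hz = series@bandHz,
    channel_labels = series@channelLabels,
    units = "uV", dtype = "float32", byte_order = "little",
    layout = "trial_channel_sample"), extra)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(dir, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(series@values, c(3L, 2L, 1L))), con,
           size = 4L, endian = "little")
  invisible(dir)
}

#' @rdname writeAlphaSeries
#' @export
readAlphaSeries <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  n <- man$n_trials * man$n_channels * man$n_samples
  con <- file(file.path(dir, "data.bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  arr <- aperm(array(x, c(man$n_samples, man$n_channels, man$n_trials)),
               c(3L, 2L, 1L))
  out <- new("AlphaSeries", values = arr,
             gridTimesMs = as.numeric(man$grid_times_ms),
             bandHz = as.numeric(man$band_hz),
             channelLabels = man$channel_labels)
  attr(out, "winMs") <- 100
  out
}
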