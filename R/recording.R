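#' Multichannel ECoG recording
#'
#' Container for a continuous subdural recording: a channels x samples
#' matrix in microvolts, the sampling rate, channel labels, one bipolar
#' EMG trace sampled at the same rate, an optional electrode-geometry
#' table and a set of excluded (artifact) channels.
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param fs sampling rate in Hz (scalar > 0).
#' @param channel_ids character or integer labels, one per data row.
#' @param emg numeric vector of EMG samples, same length as each channel.
#'   May be `NULL` when events are supplied externally.
#' @param geometry optional electrode grid (see [electrode_grid()]).
#' @param excluded_channels labels of channels to drop from analysis.
#'
#' @return An object of class `ecog_recording`.
#' @export
ecog_recording <- function(data, fs, channel_ids = NULL, emg = NULL,
                           geometry = NULL, excluded_channels = character()) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop_invalid("data must be numeric", "ecogmap_invalid_input")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_invalid("fs must be a positive scalar", "ecogmap_invalid_input")
  if (is.null(channel_ids)) channel_ids <- paste0("chan_", seq_len(nrow(data)))
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != nrow(data))
    stop_invalid("one channel id per data row required", "ecogmap_invalid_input")
  if (anyDuplicated(channel_ids))
    stop_invalid("channel ids must be unique", "ecogmap_invalid_input")
  if (!is.null(emg)) {
    emg <- as.numeric(emg)
    if (length(emg) != ncol(data))
      stop_invalid("emg must have the same number of samples as data",
                   "ecogmap_invalid_input")
  }
  excluded_channels <- as.character(excluded_channels)
  if (!all(excluded_channels %in% channel_ids))
    stop_invalid("excluded_channels must be a subset of channel_ids",
                 "ecogmap_invalid_input")
  rownames(data) <- channel_ids
  structure(list(data = data, fs = fs, channel_ids = channel_ids,
                 emg = emg, geometry = geometry,
                 excluded_channels = excluded_channels),
            class = "ecog_recording")
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf("<ecog_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (length(x$excluded_channels))
    cat("  excluded:", paste(x$excluded_channels, collapse = ", "), "\n")
  cat(sprintf("  EMG: %s; geometry: %s\n",
              if (is.null(x$emg)) "none" else "present",
              if (is.null(x$geometry)) "none" else "present"))
  invisible(x)
}

# channels actually analysed (order preserved)
usable_channels <- function(rec) {
  setdiff(rec$channel_ids, rec$excluded_channels)
}

#' Event set: EMG onset sample indices
#'
#' Onset samples are 0-based indices into the recording (time zero of each
#' trial). `source` records whether they were annotated externally or
#' detected from the EMG trace.
#'
#' @param onsets integer vector of 0-based sample indices, strictly increasing.
#' @param source `"annotated"` or `"detected"`.
#' @return An object of class `ecog_events`.
#' @export
ecog_events <- function(onsets, source = c("annotated", "detected")) {
  source <- match.arg(source)
  onsets <- as.numeric(onsets)
  if (length(onsets) && any(diff(onsets) <= 0))
    stop_invalid("onsets must be strictly increasing", "ecogmap_invalid_input")
  if (length(onsets) && any(onsets < 0))
    stop_invalid("onsets must be non-negative sample indices",
                 "ecogmap_invalid_input")
  structure(list(onsets = onsets, source = source), class = "ecog_events")
}

#' @export
print.ecog_events <- function(x, ...) {
  cat(sprintf("<ecog_events> %d onsets (%s)\n", length(x$onsets), x$source))
  invisible(x)
}

#' Read events from a two-column CSV (trial_id, onset_sample)
#' @param path CSV file path.
#' @return An [ecog_events()] object.
#' @export
read_events_csv <- function(path) {
  df <- read.csv(path)
  if (!"onset_sample" %in% names(df))
    stop_invalid(sprintf("%s: missing onset_sample column", path),
                 "ecogmap_io_error")
  ecog_events(sort(df$onset_sample), source = "annotated")
}

#' Write events to CSV
#' @param events an [ecog_events()] object.
#' @param path output CSV path.
#' @export
write_events_csv <- function(events, path) {
  write.csv(data.frame(trial_id = seq_along(events$onsets),
                       onset_sample = events$onsets),
            path, row.names = FALSE)
  invisible(path)
}
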