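#' Common average reference
#'
#' Re-references every usable channel to the instantaneous mean across
#' usable channels. Excluded (artifact) channels are left out of the
#' average and dropped from the output, so the cross-channel mean of the
#' result is exactly zero at every sample.
#'
#' @param rec an [ecog_recording()].
#' @return a re-referenced [ecog_recording()] containing only usable channels.
#' @export
apply_car <- function(rec) {
  stopifnot(inherits(rec, "ecog_recording"))
  keep <- usable_channels(rec)
  if (length(keep) < 2L)
    stop_invalid("common average reference needs at least 2 usable channels",
                 "ecogmap_invalid_input")
  d <- rec$data[keep, , drop = FALSE]
  # per-sample mean across channels; rep/each avoids sweep's aperm copy,
  # which dominates at this matrix size
  d <- d - rep(colMeans(d), each = nrow(d))
  ecog_recording(d, rec$fs, keep, emg = rec$emg, geometry = rec$geometry)
}

#' Detect EMG onsets by threshold crossing
#'
#' Rectifies the EMG (absolute value) and marks the first sample at which
#' it crosses a fraction of its maximum amplitude from below, enforcing a
#' refractory period between detections. The default fraction of 0.1
#' (one tenth of the maximum amplitude) is the standard automatic
#' alternative to visual onset marking.
#'
#' @param emg numeric EMG vector.
#' @param fs sampling rate in Hz.
#' @param threshold_frac threshold as a fraction of `max(abs(emg))`.
#' @param refractory_s minimum separation between onsets in seconds. The
#'   default of 4 s sits just below the shortest plausible inter-trial
#'   interval (5 s).
#' @return an [ecog_events()] with `source = "detected"` (0-based samples).
#' @export
detect_emg_onsets <- function(emg, fs, threshold_frac = 0.1,
                              refractory_s = 4) {
  emg <- as.numeric(emg)
  r <- abs(emg)
  peak <- max(r)
  if (peak == 0) return(ecog_events(numeric(0), source = "detected"))
  thr <- threshold_frac * peak
  above <- r >= thr
  # rising edges: below -> at/above
  rising <- which(above & !c(FALSE, above[-length(above)]))
  onsets <- numeric(0)
  last <- -Inf
  gap <- refractory_s * fs
  for (i in rising) {
    if (i - last >= gap) {
      onsets <- c(onsets, i)
      last <- i
    }
  }
  ecog_events(onsets - 1, source = "detected")  # to 0-based
}

#' Cut a recording into trials around EMG onsets
#'
#' Epochs are half-open windows `[onset - pre, onset + post)` in 0-based
#' samples; the sample at index `pre_ms * fs / 1000` within each epoch is
#' the onset sample itself (time zero). Onsets whose window overruns the
#' recording edges are dropped with a message.
#'
#' @param rec an [ecog_recording()].
#' @param events an [ecog_events()].
#' @param pre_ms,post_ms window extent before/after onset (milliseconds).
#' @return An object of class `ecog_trialset` with fields `epochs`
#'   (trials x channels x time array), `fs`, `window`, `channel_ids`,
#'   `onsets` (the kept onsets) and `keep` (logical trial mask, all
#'   `TRUE` until [reject_trials()] is applied).
#' @export
epoch_trials <- function(rec, events, pre_ms = 2000, post_ms = 4000) {
  stopifnot(inherits(rec, "ecog_recording"), inherits(events, "ecog_events"))
  pre <- round(pre_ms * rec$fs / 1000)
  post <- round(post_ms * rec$fs / 1000)
  nsamp <- ncol(rec$data)
  keep <- usable_channels(rec)
  ok <- events$onsets - pre >= 0 & events$onsets + post <= nsamp
  if (any(!ok))
    message(sprintf("epoch_trials: dropped %d onset(s) overrunning the edges",
                    sum(!ok)))
  onsets <- events$onsets[ok]
  if (!length(onsets))
    stop_invalid("no onset leaves a full epoch inside the recording",
                 "ecogmap_empty_result")
  nt <- length(onsets)
  len <- pre + post
  epochs <- array(NA_real_, dim = c(nt, length(keep), len),
                  dimnames = list(NULL, keep, NULL))
  for (ti in seq_len(nt)) {
    idx <- (onsets[ti] - pre + 1):(onsets[ti] + post)  # 1-based slice
    epochs[ti, , ] <- rec$data[keep, idx, drop = FALSE]
  }
  structure(list(epochs = epochs, fs = rec$fs,
                 window = c(pre_ms = pre_ms, post_ms = post_ms),
                 channel_ids = keep, onsets = onsets,
                 keep = rep(TRUE, nt)),
            class = "ecog_trialset")
}

#' @export
print.ecog_trialset <- function(x, ...) {
  cat(sprintf(
    "<ecog_trialset> %d trials (%d kept) x %d channels x %d samples @ %g Hz, window [-%g, +%g] ms\n",
    dim(x$epochs)[1], sum(x$keep), dim(x$epochs)[2], dim(x$epochs)[3],
    x$fs, x$window[["pre_ms"]], x$window[["post_ms"]]))
  invisible(x)
}

# kept-trial epochs for one channel: trials x time matrix
channel_trials <- function(ts, channel) {
  ch <- if (is.character(channel)) match(channel, ts$channel_ids) else channel
  if (is.na(ch) || ch < 1 || ch > dim(ts$epochs)[2])
    stop_invalid("unknown channel", "ecogmap_invalid_input")
  ts$epochs[ts$keep, ch, , drop = FALSE][, 1, , drop = TRUE]
}

# sample slice (1-based, into the epoch) for a time window relative to
# onset, half-open [from_ms, to_ms)
epoch_slice <- function(ts, from_ms, to_ms) {
  t0 <- round(ts$window[["pre_ms"]] * ts$fs / 1000)  # 0-based time-zero index
  from <- t0 + round(from_ms * ts$fs / 1000)
  to <- t0 + round(to_ms * ts$fs / 1000)
  if (from < 0 || to > dim(ts$epochs)[3])
    stop_invalid(sprintf("window [%g, %g) ms outside the epoch", from_ms, to_ms),
                 "ecogmap_invalid_configuration")
  (from + 1):to
}

#' Mask trials with outlying peak amplitude
#'
#' Automated stand-in for visual artifact screening: the peak absolute
#' amplitude of each trial (across channels) is scored as a robust
#' z-value (median/MAD of the per-trial peak distribution) and trials
#' exceeding `amplitude_z_max` are masked out. Data are retained; only
#' the `keep` mask changes.
#'
#' @param ts an `ecog_trialset`.
#' @param amplitude_z_max robust z threshold (default 5).
#' @return the trial set with an updated `keep` mask.
#' @export
reject_trials <- function(ts, amplitude_z_max = 5) {
  stopifnot(inherits(ts, "ecog_trialset"))
  if (!any(ts$keep))
    stop_invalid("no trials to screen", "ecogmap_empty_result")
  peaks <- vapply(seq_len(dim(ts$epochs)[1]),
                  function(ti) max(abs(ts$epochs[ti, , ])), numeric(1))
  med <- stats::median(peaks[ts$keep])
  madv <- stats::mad(peaks[ts$keep])
  # MAD of 0 (e.g. identical clean trials) must still catch a gross spike
  denom <- max(madv, .Machine$double.eps * max(med, 1))
  z <- abs(peaks - med) / denom
  ts$keep <- ts$keep & (z <= amplitude_z_max)
  if (!any(ts$keep))
    stop_invalid("all trials rejected", "ecogmap_empty_result")
  ts
}
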