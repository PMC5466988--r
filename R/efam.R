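# Frequency alteration mapping: task-versus-rest spectral power change
# in the mu/beta band (8-32 Hz) and the gamma band (66-90 Hz), scored by
# a signed squared cross-correlation weight with ANOVA significance.

EFAM_TASK_WINDOW_MS <- c(0, 1000)
EFAM_REST_WINDOW_MS <- c(-3500, -2500)
LFB_BAND <- c(8, 32)
HFB_BAND <- c(66, 90)

#' Extract 1 s task and rest segments per trial
#'
#' The task segment is the 1,000 ms following the EMG onset; the rest
#' segment is -3,500 to -2,500 ms before it, so the trial set must have
#' been epoched with `pre_ms >= 3500`.
#'
#' @param ts an `ecog_trialset` whose window covers -3500..+1000 ms.
#' @param channel channel label or index.
#' @return list of matrices `task` and `rest`, each kept-trials x
#'   `fs` samples.
#' @export
spectral_segments <- function(ts, channel) {
  if (ts$window[["pre_ms"]] < -EFAM_REST_WINDOW_MS[1] ||
      ts$window[["post_ms"]] < EFAM_TASK_WINDOW_MS[2])
    stop_invalid(
      "epoch window too short: spectral mapping needs pre >= 3500 ms and post >= 1000 ms",
      "ecogmap_invalid_configuration")
  tr <- channel_trials(ts, channel)
  if (is.null(dim(tr))) tr <- matrix(tr, nrow = 1L)
  task_idx <- epoch_slice(ts, EFAM_TASK_WINDOW_MS[1], EFAM_TASK_WINDOW_MS[2])
  rest_idx <- epoch_slice(ts, EFAM_REST_WINDOW_MS[1], EFAM_REST_WINDOW_MS[2])
  list(task = tr[, task_idx, drop = FALSE],
       rest = tr[, rest_idx, drop = FALSE])
}

#' Power spectrum of a 1 s segment
#'
#' Single Hanning-tapered FFT power spectrum (no Welch averaging): a 1 s
#' segment gives a 1 Hz frequency grid, the resolution at which the
#' 25-bin analysis bands are defined.
#'
#' @param segment numeric vector of exactly `fs` samples.
#' @param fs sampling rate in Hz.
#' @return list with `f` (0..fs/2 Hz) and `power`.
#' @export
segment_psd <- function(segment, fs) {
  n <- length(segment)
  if (n != round(fs))
    stop_invalid("segment must be exactly 1 s long", "ecogmap_invalid_input")
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))  # Hanning
  sp <- fft(segment * w)
  nf <- floor(n / 2) + 1
  p <- abs(sp[1:nf])^2 / sum(w^2)
  # fold negative frequencies into the one-sided spectrum
  if (n %% 2 == 0) p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
  else p[2:nf] <- 2 * p[2:nf]
  list(f = (0:(nf - 1)) * fs / n, power = p)
}

#' Ensemble log-normalisation of segment spectra
#'
#' Divides every spectral sample by the mean over the whole ensemble
#' (all task and rest segments together) at that frequency, then takes
#' the natural log. By construction the per-frequency mean of
#' `exp(normalised)` over segments is 1, removing the 1/f power-law tilt
#' that would otherwise let low frequencies dominate band sums.
#'
#' @param P matrix of linear power, segments x frequencies.
#' @return matrix of normalised log power, same shape.
#' @export
normalize_psd <- function(P) {
  P <- as.matrix(P)
  mu <- colMeans(P)
  if (any(!is.finite(mu)) || any(mu <= 0) || any(P <= 0))
    stop_invalid("power must be strictly positive at analysed frequencies",
                 "ecogmap_degenerate")
  log(P) - rep(log(mu), each = nrow(P))
}

#' Band sum of normalised power
#'
#' Inclusive sum over the integer-Hz bins `band[1]..band[2]` (25 bins
#' for each default band) of each segment's normalised spectrum.
#'
#' @param Pn normalised power matrix (segments x frequencies).
#' @param band `c(lo, hi)` in Hz.
#' @param f frequency grid matching the columns of `Pn` (default
#'   `0:(ncol - 1)` Hz, the 1 s segment grid).
#' @return numeric vector, one sum per segment.
#' @export
band_sum <- function(Pn, band, f = NULL) {
  Pn <- as.matrix(Pn)
  if (is.null(f)) f <- 0:(ncol(Pn) - 1)
  if (band[1] > band[2] || band[1] < min(f) || band[2] > max(f))
    stop_invalid("band outside the spectrum range", "ecogmap_invalid_parameter")
  sel <- f >= band[1] & f <= band[2]
  rowSums(Pn[, sel, drop = FALSE])
}

#' Signed activation weight between task and rest band power
#'
#' `A = sign(mean(m) - mean(r)) * (mean(m) - mean(r))^2 / var(m u r) *
#' Nm * Nr / N^2`, with the population (divide-by-N) variance of the
#' pooled sample. This is the signed squared point-biserial correlation
#' between the pooled values and the group label, so `A` lies in
#' `[-1, 1]`; negative values mean a task power decrease
#' (desynchronisation), positive an increase.
#'
#' @param m,r numeric vectors of task and rest band sums (length >= 2 each).
#' @return signed weight in `[-1, 1]`.
#' @export
activation_weight <- function(m, r) {
  nm <- length(m); nr <- length(r)
  if (nm < 2L || nr < 2L)
    stop_invalid("need at least 2 task and 2 rest values",
                 "ecogmap_invalid_input")
  mbar <- mean(m); rbar <- mean(r)
  u <- c(m, r)
  n <- nm + nr
  v <- sum((u - mean(u))^2) / n  # population variance of the union
  if (v == 0) {
    if (mbar == rbar) return(0)
    stop_invalid("zero pooled variance with unequal means",
                 "ecogmap_degenerate")
  }
  sign(mbar - rbar) * (mbar - rbar)^2 / v * nm * nr / n^2
}

#' Map every channel by spectral band power change
#'
#' For each channel: per-trial task and rest segments are
#' Hanning-tapered into 1 Hz power spectra, log-normalised over the
#' joint ensemble, summed over each analysis band, contrasted by the
#' signed activation weight and a balanced one-way ANOVA. Bonferroni
#' correction is per band across channels by default (`"per_band"`);
#' `"pooled"` multiplies by bands x channels instead.
#'
#' A channel is spectrally positive (`efam_positive()`) when either band
#' (or both) is significant.
#'
#' @param ts an `ecog_trialset` epoched with `pre_ms >= 3500`.
#' @param bands named list of `c(lo, hi)` bands (defaults: LFB 8-32 Hz,
#'   HFB 66-90 Hz).
#' @param alpha corrected significance level (default 0.01).
#' @param correction `"per_band"` or `"pooled"`.
#' @return a `data.frame` (class `efam_scores`): `channel`, `band`, `A`,
#'   `F`, `p_raw`, `p_corrected`, `significant`.
#' @export
efam_map <- function(ts, bands = list(LFB = LFB_BAND, HFB = HFB_BAND),
                     alpha = 0.01, correction = c("per_band", "pooled")) {
  correction <- match.arg(correction)
  chans <- ts$channel_ids
  n_tests <- if (correction == "per_band") length(chans)
             else length(chans) * length(bands)
  rows <- list()
  for (ch in chans) {
    seg <- spectral_segments(ts, ch)
    all_seg <- rbind(seg$task, seg$rest)
    P <- t(apply(all_seg, 1L, function(s) segment_psd(s, ts$fs)$power))
    nf <- ncol(P)
    f <- (0:(nf - 1)) * ts$fs / round(ts$fs)
    # drop any zero-power bins (DC of a demeaned segment, etc.) from the
    # ensemble before the log step
    pos <- apply(P > 0, 2L, all)
    Pn <- normalize_psd(P[, pos, drop = FALSE])
    fpos <- f[pos]
    nt <- nrow(seg$task)
    for (bn in names(bands)) {
      m <- band_sum(Pn[seq_len(nt), , drop = FALSE], bands[[bn]], fpos)
      r <- band_sum(Pn[nt + seq_len(nrow(seg$rest)), , drop = FALSE],
                    bands[[bn]], fpos)
      A <- activation_weight(m, r)
      sig <- channel_significance(m, r, n_tests, alpha = alpha)
      rows[[length(rows) + 1L]] <-
        data.frame(channel = ch, band = bn, A = A, F = sig$F,
                   p_raw = sig$p_raw, p_corrected = sig$p_corrected,
                   significant = sig$significant)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("efam_scores", "data.frame")
  out
}

#' Channels positive in either spectral band
#' @param scores an `efam_scores` data frame from [efam_map()].
#' @return character vector of channels significant in LFB, HFB or both.
#' @export
efam_positive <- function(scores) {
  unique(scores$channel[scores$significant])
}
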