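# Temporal alteration mapping: MRCP template correlation scored per
# channel with a signed R-squared statistic.
#
# Per trial, the 0-500 ms post-onset segment (motor potential + first
# movement-related response) is correlated with a 500 ms template, as is
# the -2000..-1500 ms rest segment. Per channel the two correlation sets
# are contrasted by the signed R2 (between-group over total sum of
# squares, signed by the direction of the mean difference) and a
# balanced one-way ANOVA with Bonferroni correction across channels.

TASK_WINDOW_MS <- c(0, 500)
REST_WINDOW_MS <- c(-2000, -1500)
BASELINE_WINDOW_MS <- c(-2000, -1600)

#' Grand-average waveform of one channel
#'
#' Mean over kept trials, baseline-corrected by the mean of the
#' -2000..-1600 ms pre-onset segment (the first 400 ms of the standard
#' epoch window).
#'
#' @param ts an `ecog_trialset`.
#' @param channel channel label or index.
#' @return An object of class `ecog_grand_average`: `waveform` (full
#'   epoch, baseline removed), `baseline` (the subtracted scalar),
#'   `n_trials`, `fs`, `window`, `channel`.
#' @export
grand_average <- function(ts, channel) {
  if (!any(ts$keep))
    stop_invalid("no kept trials", "ecogmap_empty_result")
  tr <- channel_trials(ts, channel)
  if (is.null(dim(tr))) tr <- matrix(tr, nrow = 1L)
  w <- colMeans(tr)
  bl <- mean(w[epoch_slice(ts, BASELINE_WINDOW_MS[1], BASELINE_WINDOW_MS[2])])
  structure(list(waveform = w - bl, baseline = bl, n_trials = nrow(tr),
                 fs = ts$fs, window = ts$window, channel = channel),
            class = "ecog_grand_average")
}

#' Pick the representative MRCP channel of a subject
#'
#' The channel whose baseline-corrected grand average has the largest
#' peak absolute amplitude inside the 0-500 ms task window. Ties go to
#' the lowest channel index; a peak below `floor_uv` flags the choice as
#' low-confidence (attribute `low_confidence`), e.g. on a pure-noise
#' array.
#'
#' @param ts an `ecog_trialset`.
#' @param floor_uv confidence floor in microvolts.
#' @return channel label (character) with attributes `peak_uv` and
#'   `low_confidence`.
#' @export
select_representative <- function(ts, floor_uv = 5) {
  peaks <- vapply(ts$channel_ids, function(ch) {
    ga <- grand_average(ts, ch)
    idx <- epoch_slice(ts, TASK_WINDOW_MS[1], TASK_WINDOW_MS[2])
    max(abs(ga$waveform[idx]))
  }, numeric(1))
  best <- which.max(peaks)  # which.max takes the first (lowest index) on ties
  out <- ts$channel_ids[best]
  attr(out, "peak_uv") <- unname(peaks[best])
  attr(out, "low_confidence") <- unname(peaks[best] < floor_uv)
  out
}

#' Build the 500 ms MRCP template
#'
#' Element-wise mean of the representative grand averages (one per
#' subject), restricted to its 0-500 ms post-onset segment.
#'
#' @param reps list of `ecog_grand_average` objects with equal sampling
#'   rates and windows.
#' @return An object of class `ecog_template`: `waveform` (length
#'   `0.5 * fs`), `fs`, `provenance` (channels used), `mean` (cached).
#' @export
build_template <- function(reps) {
  if (!length(reps)) stop_invalid("need at least one representative",
                                  "ecogmap_invalid_input")
  fs <- unique(vapply(reps, `[[`, numeric(1), "fs"))
  if (length(fs) != 1L)
    stop_invalid("representatives have mixed sampling rates",
                 "ecogmap_invalid_input")
  lens <- unique(lengths(lapply(reps, `[[`, "waveform")))
  if (length(lens) != 1L)
    stop_invalid("representatives have mixed epoch lengths",
                 "ecogmap_invalid_input")
  mean_wave <- rowMeans(vapply(reps, `[[`, numeric(lens), "waveform"))
  pre <- round(reps[[1]]$window[["pre_ms"]] * fs / 1000)
  seg <- mean_wave[(pre + 1):(pre + round(0.5 * fs))]
  structure(list(waveform = seg, fs = fs,
                 provenance = vapply(reps, function(r) as.character(r$channel),
                                     character(1)),
                 mean = mean(seg)),
            class = "ecog_template")
}

#' Leave-one-subject-out template
#'
#' Cross-validation template: the mean of every subject's representative
#' grand average except the held-out subject's.
#'
#' @param reps named/ordered list of `ecog_grand_average`, one per subject.
#' @param held_out index (or name) of the subject to exclude.
#' @return an `ecog_template` built from the remaining subjects.
#' @export
loso_template <- function(reps, held_out) {
  if (length(reps) < 2L)
    stop_invalid("cross-validation needs at least 2 subjects",
                 "ecogmap_invalid_input")
  if (is.character(held_out)) held_out <- match(held_out, names(reps))
  if (is.na(held_out) || held_out < 1 || held_out > length(reps))
    stop_invalid("held_out does not name a subject", "ecogmap_invalid_input")
  build_template(reps[-held_out])
}

#' Pearson correlation coefficient
#'
#' Product-moment correlation between two equal-length vectors; the
#' trial-versus-template similarity measure.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in `[-1, 1]`, or `NA` (with a
#'   `ecogmap_degenerate` warning) when either input has zero variance.
#' @export
correlation_coefficient <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop_invalid("x and y must have equal length >= 2", "ecogmap_invalid_input")
  sx <- sum((x - mean(x))^2)
  sy <- sum((y - mean(y))^2)
  if (sx == 0 || sy == 0) {
    warning(structure(
      class = c("ecogmap_degenerate", "warning", "condition"),
      list(message = "zero-variance input to correlation", call = sys.call())))
    return(NA_real_)
  }
  sum((x - mean(x)) * (y - mean(y))) / sqrt(sx * sy)
}

#' Per-trial task and rest correlations with the template
#'
#' For every kept trial of one channel: `q[i]` is the correlation of the
#' 0-500 ms task component with the template, `t[i]` the correlation of
#' the -2000..-1500 ms rest component. Trials in which either component
#' (or a degenerate template) yields an undefined correlation are dropped
#' from both vectors so they stay balanced.
#'
#' @param ts an `ecog_trialset`.
#' @param channel channel label or index.
#' @param tmpl an `ecog_template`.
#' @return list with numeric `q`, `t` (equal length) and `n_dropped`.
#' @export
trial_ccs <- function(ts, channel, tmpl) {
  stopifnot(inherits(tmpl, "ecog_template"))
  if (stats::var(tmpl$waveform) == 0)
    stop_invalid("degenerate (zero-variance) template", "ecogmap_degenerate")
  tr <- channel_trials(ts, channel)
  if (is.null(dim(tr))) tr <- matrix(tr, nrow = 1L)
  task_idx <- epoch_slice(ts, TASK_WINDOW_MS[1], TASK_WINDOW_MS[2])
  rest_idx <- epoch_slice(ts, REST_WINDOW_MS[1], REST_WINDOW_MS[2])
  if (length(task_idx) != length(tmpl$waveform))
    stop_invalid("template length does not match the task component",
                 "ecogmap_invalid_input")
  q <- t_ <- numeric(nrow(tr))
  ok <- logical(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    qi <- suppressWarnings(correlation_coefficient(tr[i, task_idx],
                                                   tmpl$waveform))
    ti <- suppressWarnings(correlation_coefficient(tr[i, rest_idx],
                                                   tmpl$waveform))
    ok[i] <- !is.na(qi) && !is.na(ti)
    if (ok[i]) { q[i] <- qi; t_[i] <- ti }
  }
  if (any(!ok))
    message(sprintf("trial_ccs: dropped %d degenerate trial(s)", sum(!ok)))
  list(q = q[ok], t = t_[ok], n_dropped = sum(!ok))
}

#' Signed R-squared between task and rest correlation sets
#'
#' Between-group sum of squares over total sum of squares of the two
#' balanced samples, with the grand correction term
#' `G = (sum(q) + sum(t))^2 / (2n)`:
#' `R2 = ((sum(q))^2/n + (sum(t))^2/n - G) / (sum(q^2) + sum(t^2) - G)`.
#' The magnitude equals the squared point-biserial correlation between
#' the pooled values and the group label; the sign is that of
#' `mean(q) - mean(t)`, so a channel whose task segments track the
#' (negative-going) MRCP template better than its rest segments scores
#' positive — a positive value means a negative cortical potential.
#'
#' @param q,t equal-length numeric vectors (task and rest correlations).
#' @return signed R2 in `[-1, 1]`; `NA` with a warning when the total
#'   variance is zero.
#' @export
signed_r2 <- function(q, t) {
  n <- length(q)
  if (length(t) != n || n < 2L)
    stop_invalid("q and t must have equal length >= 2", "ecogmap_invalid_input")
  G <- (sum(q) + sum(t))^2 / (2 * n)
  denom <- sum(q^2) + sum(t^2) - G
  if (denom <= 0) {
    if (isTRUE(all.equal(mean(q), mean(t)))) return(0)
    warning(structure(
      class = c("ecogmap_degenerate", "warning", "condition"),
      list(message = "zero total variance in signed_r2", call = sys.call())))
    return(NA_real_)
  }
  r2 <- (sum(q)^2 / n + sum(t)^2 / n - G) / denom
  sign(mean(q) - mean(t)) * r2
}

#' ANOVA significance of the task/rest correlation contrast
#'
#' Balanced one-way (two-group) ANOVA of `q` versus `t`: an F test with
#' 1 and `2n - 2` degrees of freedom, Bonferroni-corrected across the
#' analysed channels. The F statistic relates to the signed R2 through
#' `F = |R2| / (1 - |R2|) * (2n - 2)`.
#'
#' @param q,t equal-length numeric vectors.
#' @param n_channels number of channels analysed (Bonferroni factor).
#' @param alpha significance level on the corrected p (default 0.01).
#' @return list with `F`, `p_raw`, `p_corrected`, `significant`.
#' @export
channel_significance <- function(q, t, n_channels, alpha = 0.01) {
  n <- length(q)
  if (length(t) != n || n < 2L)
    stop_invalid("q and t must have equal length >= 2", "ecogmap_invalid_input")
  gm <- mean(c(q, t))
  ssb <- n * ((mean(q) - gm)^2 + (mean(t) - gm)^2)
  ssw <- sum((q - mean(q))^2) + sum((t - mean(t))^2)
  df2 <- 2 * n - 2
  if (ssw == 0) {
    f <- if (ssb == 0) 0 else Inf
  } else {
    f <- (ssb / 1) / (ssw / df2)
  }
  p_raw <- pf(f, 1, df2, lower.tail = FALSE)
  p_corrected <- min(1, p_raw * n_channels)
  list(F = f, p_raw = p_raw, p_corrected = p_corrected,
       significant = p_corrected < alpha)
}

#' Map every channel by template correlation
#'
#' Runs the task/rest correlation contrast on each channel of a trial
#' set and collects per-channel scores: the per-trial correlation
#' vectors, the signed R2, and ANOVA significance Bonferroni-corrected
#' across the channels actually analysed.
#'
#' @param ts an `ecog_trialset` (band-passed, re-referenced, epoched).
#' @param tmpl an `ecog_template`.
#' @param alpha corrected significance level (default 0.01).
#' @return a `data.frame` (class `etam_scores`) with one row per channel:
#'   `channel`, `n` (balanced trial count), `r2`, `F`, `p_raw`,
#'   `p_corrected`, `significant`, `analyzable`. The per-channel `q`/`t`
#'   vectors are kept in the `"cc"` attribute.
#' @export
etam_map <- function(ts, tmpl, alpha = 0.01) {
  chans <- ts$channel_ids
  cc <- lapply(chans, function(ch) trial_ccs(ts, ch, tmpl))
  names(cc) <- chans
  n_kept <- sum(ts$keep)
  analyzable <- vapply(cc, function(x) {
    length(x$q) >= 2 && x$n_dropped <= 0.5 * n_kept
  }, logical(1))
  n_tests <- sum(analyzable)
  rows <- lapply(seq_along(chans), function(i) {
    if (!analyzable[i])
      return(data.frame(channel = chans[i], n = length(cc[[i]]$q),
                        r2 = NA_real_, F = NA_real_, p_raw = NA_real_,
                        p_corrected = NA_real_, significant = FALSE,
                        analyzable = FALSE))
    q <- cc[[i]]$q; t_ <- cc[[i]]$t
    r2 <- signed_r2(q, t_)
    sig <- channel_significance(q, t_, n_tests, alpha = alpha)
    data.frame(channel = chans[i], n = length(q), r2 = r2, F = sig$F,
               p_raw = sig$p_raw, p_corrected = sig$p_corrected,
               significant = sig$significant, analyzable = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cc") <- cc
  attr(out, "alpha") <- alpha
  class(out) <- c("etam_scores", "data.frame")
  out
}

#' Export / import a template as CSV with a JSON sidecar
#'
#' The CSV holds `time_ms, amplitude_uV`; the sidecar `<path>.json`
#' stores the sampling rate and provenance.
#'
#' @param tmpl an `ecog_template`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_template_csv <- function(tmpl, path) {
  tms <- (seq_along(tmpl$waveform) - 1) / tmpl$fs * 1000
  write.csv(data.frame(time_ms = tms, amplitude_uV = tmpl$waveform),
            path, row.names = FALSE)
  jsonlite::write_json(list(fs = tmpl$fs, provenance = tmpl$provenance),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_template_csv
#' @export
read_template_csv <- function(path) {
  df <- read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(waveform = df$amplitude_uV, fs = side$fs,
                 provenance = side$provenance,
                 mean = mean(df$amplitude_uV)),
            class = "ecog_template")
}
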