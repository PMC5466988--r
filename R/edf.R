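# Minimal European Data Format (EDF) I/O: continuous 16-bit recordings,
# all signals at one sampling rate, 1 s data records. No EDF library is
# available in the target environment, and the format is a fixed-layout
# 16-bit container, so reading and writing are implemented directly.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)  # left-justified, space padded
}

#' Write a recording as an EDF file
#'
#' All ECoG channels plus (when present) a final signal labelled `EMG`
#' are stored as 16-bit integers over a per-signal physical range with a
#' small margin, in 1 s data records; the tail is zero-padded to a whole
#' record. Quantisation error is at most one digital step of
#' `(phys_max - phys_min) / 65535`.
#'
#' @param rec an [ecog_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "ecog_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop_invalid("EDF writer requires an integer sampling rate",
                 "ecogmap_io_error")
  fs <- round(fs)
  sig <- rec$data
  labels <- rec$channel_ids
  if (!is.null(rec$emg)) {
    sig <- rbind(sig, rec$emg)
    labels <- c(labels, "EMG")
  }
  ns <- nrow(sig)
  n <- ncol(sig)
  n_rec <- ceiling(n / fs)
  if (n_rec * fs > n)
    sig <- cbind(sig, matrix(0, nrow = ns, ncol = n_rec * fs - n))
  pmin_ <- apply(sig, 1L, min)
  pmax_ <- apply(sig, 1L, max)
  span <- pmax_ - pmin_
  # rounded to 2 decimals so the 8-char header field is exact, with a
  # margin so no sample sits on the range edge
  pmin_ <- floor((pmin_ - pmax(0.05 * span, 1e-2)) * 100) / 100
  pmax_ <- ceiling((pmax_ + pmax(0.05 * span, 1e-2)) * 100) / 100
  if (any(abs(c(pmin_, pmax_)) >= 1e4))
    stop_invalid("signal amplitudes exceed the supported EDF header width",
                 "ecogmap_io_error")
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)                              # version
  wr("X X X X", 80)                       # patient id (anonymous)
  wr("Startdate X X X X", 80)             # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)    # date, time
  wr(256 * (ns + 1), 8)                   # header bytes
  wr("", 44)                              # reserved
  wr(n_rec, 8)
  wr("1", 8)                              # record duration (s)
  wr(ns, 4)
  for (l in labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)       # transducer
  for (i in seq_len(ns)) wr("uV", 8)
  for (v in pmin_) wr(formatC(v, digits = 2, format = "f"), 8)
  for (v in pmax_) wr(formatC(v, digits = 2, format = "f"), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)       # prefilter
  for (i in seq_len(ns)) wr(fs, 8)        # samples per record
  for (i in seq_len(ns)) wr("", 32)       # reserved

  gain <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((sig[i, idx] - pmin_[i]) * gain[i]) + dmin
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Supports the subset written by [write_edf()]: uniform sampling rate,
#' 16-bit continuous records. A signal whose label equals `emg_label`
#' is split out as the EMG trace.
#'
#' @param path EDF file path.
#' @param emg_label label identifying the EMG signal (default `"EMG"`;
#'   `NULL` keeps every signal as a data channel).
#' @return an [ecog_recording()].
#' @export
read_edf <- function(path, emg_label = "EMG") {
  if (!file.exists(path))
    stop_invalid(sprintf("EDF file not found: %s", path), "ecogmap_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop_invalid(sprintf("%s: mixed per-signal sampling rates unsupported",
                         path), "ecogmap_io_error")
  fs <- spr[1] / rec_dur
  sig <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      idx <- ((r - 1) * spr[i] + 1):(r * spr[i])
      sig[i, idx] <- (dig - dmin[i]) * gain[i] + pmin_[i]
    }
  }
  emg <- NULL
  if (!is.null(emg_label) && emg_label %in% labels) {
    emg <- sig[labels == emg_label, ]
    sig <- sig[labels != emg_label, , drop = FALSE]
    labels <- labels[labels != emg_label]
  }
  ecog_recording(sig, fs, labels, emg = emg)
}
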