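# Butterworth design and zero-phase IIR filtering.
#
# No DSP package ships with the target environment, so the classical
# design chain is implemented here: analog prototype -> band transform in
# zero-pole-gain form -> bilinear transform -> polynomial coefficients,
# plus scipy-style filtfilt (odd-reflection padding with steady-state
# initial conditions).

# polynomial with given roots, leading coefficient 1 (complex-safe)
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - ri * c(0, p)
  p
}

#' Butterworth filter design
#'
#' Digital Butterworth coefficients via the bilinear transform with
#' frequency pre-warping, as used throughout EEG/ECoG processing.
#'
#' @param n filter order (of the analog prototype; a band-pass of order
#'   `n` has `2n` poles).
#' @param w critical frequency in Hz (scalar for low/high-pass, length-2
#'   `c(lo, hi)` for band-pass).
#' @param fs sampling rate in Hz.
#' @param type `"pass"` or `"low"`.
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
butter_filter <- function(n, w, fs, type = c("pass", "low")) {
  type <- match.arg(type)
  if (any(w <= 0) || any(w >= fs / 2))
    stop_invalid("critical frequencies must lie in (0, fs/2)",
                 "ecogmap_invalid_parameter")
  # analog prototype: n poles on the unit circle, left half-plane
  k <- 1:n
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  z <- complex(0)
  g <- 1
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  if (type == "pass") {
    if (length(w) != 2L || w[1] >= w[2])
      stop_invalid("band-pass needs w = c(lo, hi) with lo < hi",
                   "ecogmap_invalid_parameter")
    w1 <- warp(w[1]); w2 <- warp(w[2])
    bw <- w2 - w1; w0 <- sqrt(w1 * w2)
    g <- g * bw^n
    ph <- p * bw / 2
    p <- c(ph + sqrt(ph^2 - w0^2), ph - sqrt(ph^2 - w0^2))
    z <- rep(0 + 0i, n)
  } else {
    wc <- warp(w[1])
    p <- p * wc
    g <- g * wc^n
  }
  # bilinear transform s -> 2*fs*(z-1)/(z+1)
  fs2 <- 2 * fs
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  gd <- g * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- c(zd, rep(-1 + 0i, length(p) - length(z)))
  b <- Re(gd * poly_from_roots(zd))
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

#' Analytic squared-magnitude response of a Butterworth band-pass
#'
#' `|H(f)|^2 = 1 / (1 + ((f^2 - lo*hi) / ((hi - lo) * f))^(2n))`, the
#' classical band-pass magnitude; used as the independent oracle for the
#' zero-phase (forward-backward) filter whose effective gain is `|H|^2`.
#'
#' @param f frequency in Hz.
#' @param lo,hi band edges in Hz.
#' @param n prototype order.
#' @return squared magnitude (single-pass) at `f`.
#' @export
butter_bandpass_gain2 <- function(f, lo, hi, n = 2) {
  1 / (1 + ((f^2 - lo * hi) / ((hi - lo) * f))^(2 * n))
}

# steady-state initial state so a step input produces a step output
# (companion-matrix solve, as in scipy.signal.lfilter_zi)
lfilter_zi <- function(b, a) {
  nf <- length(a)
  comp <- matrix(0, nf - 1, nf - 1)
  comp[1, ] <- -a[-1] / a[1]
  if (nf > 2) comp[cbind(2:(nf - 1), 1:(nf - 2))] <- 1
  B <- b[-1] - a[-1] * b[1]
  as.numeric(solve(diag(nf - 1) - t(comp), B))
}

#' Zero-phase IIR filtering
#'
#' Applies the filter forward and backward so the net phase is zero and
#' the effective magnitude response is the squared single-pass response.
#' Edges are handled by odd reflection padding with steady-state initial
#' conditions.
#'
#' @param b,a filter coefficients as from [butter_filter()].
#' @param x numeric vector.
#' @param padlen reflection padding length (samples); default
#'   `3 * max(length(a), length(b))`.
#' @return filtered vector, same length as `x`.
#' @export
filtfilt_zero_phase <- function(b, a, x, padlen = NULL) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b)))
  a <- c(a, rep(0, nf - length(a)))
  if (a[1] != 1) { b <- b / a[1]; a <- a / a[1] }
  if (is.null(padlen)) padlen <- 3 * nf
  n <- length(x)
  if (padlen >= n)
    stop_invalid("signal too short for the requested padding",
                 "ecogmap_invalid_input")
  zi <- lfilter_zi(b, a)
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  y <- lfilter_state(b, a, ext, zi * ext[1])$y
  y <- lfilter_state(b, a, y, zi * y[length(y)], reverse = TRUE)$y
  y[(padlen + 1):(padlen + n)]
}

#' Band-pass filter a recording into the slow cortical potential band
#'
#' Zero-phase 2nd order Butterworth band-pass (default 0.05-3 Hz), the
#' band in which the movement-related cortical potential lives. Zero
#' phase is essential here: the downstream template correlation scores
#' waveform latency, which a causal filter would shift.
#'
#' @param rec an [ecog_recording()].
#' @param low,high band edges in Hz.
#' @param order Butterworth prototype order.
#' @param padlen edge padding passed to [filtfilt_zero_phase()]; defaults
#'   to `min(10 * fs, n - 1)` because the low edge settles slowly.
#' @return a filtered copy of the recording (EMG left untouched).
#' @export
bandpass_mrcp <- function(rec, low = 0.05, high = 3, order = 2,
                          padlen = NULL) {
  stopifnot(inherits(rec, "ecog_recording"))
  if (high >= rec$fs / 2)
    stop_invalid("high edge must be below Nyquist", "ecogmap_invalid_parameter")
  if (low <= 0 || low >= high)
    stop_invalid("need 0 < low < high", "ecogmap_invalid_parameter")
  coef <- butter_filter(order, c(low, high), rec$fs, "pass")
  n <- ncol(rec$data)
  if (is.null(padlen)) padlen <- min(round(10 * rec$fs), n - 1)
  d <- rec$data
  for (i in seq_len(nrow(d)))
    d[i, ] <- filtfilt_zero_phase(coef$b, coef$a, d[i, ], padlen = padlen)
  out <- rec
  out$data <- d
  out
}
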