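# Synthetic multichannel ECoG + EMG generator with ground truth.
#
# Emulates the intraoperative protocol: 2,000 Hz sampling, 4 mm
# electrodes at 10 mm pitch (4 x 8 grid by default), 40 brisk wrist
# extension trials at 5-16 s inter-trial intervals. Designated channels
# carry a movement-related cortical potential (slow negativity peaking
# ~100 ms after EMG onset), an 8-32 Hz power decrease and/or a 66-90 Hz
# power increase for ~1 s after onset; all channels share a 1/f
# background and per-channel mu/beta and gamma rhythms. One seed fixes
# all randomness.

#' Simulation configuration
#'
#' Defaults restate the recording protocol: a 4 x 8 grid at 10 mm pitch,
#' fs = 2000 Hz, 40 trials, inter-trial intervals uniform in 5-16 s.
#' Effect channels form a small adjacent cluster as on a real motor
#' strip; the stimulation-positive ground truth is the MRCP cluster by
#' construction.
#'
#' @param n_rows,n_cols grid layout (default 4 x 8 = 32 channels).
#' @param pitch_mm inter-electrode distance (mm).
#' @param fs sampling rate (Hz).
#' @param n_trials number of movement trials.
#' @param iti_range inter-trial interval range in seconds.
#' @param mrcp_channels indices of channels carrying the MRCP.
#' @param mrcp_amplitude_uV peak MRCP negativity in microvolts.
#' @param erd_channels indices with an 8-32 Hz power decrease.
#' @param erd_depth fractional amplitude attenuation of the mu/beta
#'   rhythm during the task second (0.5 = power drops to 25 %).
#' @param ers_channels indices with a 66-90 Hz power increase.
#' @param ers_gain fractional amplitude gain of the gamma rhythm during
#'   the task second (1 = amplitude doubles, power x4).
#' @param noise_scale_uV broadband background standard deviation.
#' @param noise_exponent 1/f^a spectral exponent of the background.
#' @param noise_knee_hz spectrum flattens below this frequency.
#' @param lfb_rhythm_uV standard deviation of the band-limited mu/beta
#'   rhythm present on every channel (sensorimotor rhythms are
#'   widespread).
#' @param hfb_rhythm_uV standard deviation of the narrowband gamma
#'   component carried by ERS channels; elsewhere the 66-90 Hz content
#'   is just the 1/f background, matching the broadband view of ECoG
#'   gamma.
#' @param line_noise_uV 50 Hz line amplitude (default 0: the amplifier
#'   notch is assumed).
#' @param line_freq_hz line frequency.
#' @param saturation_uV optional clipping level emulating amplifier
#'   saturation (`Inf` = off).
#' @param seed integer seed fixing all randomness.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_rows = 4, n_cols = 8, pitch_mm = 10, fs = 2000,
                       n_trials = 40, iti_range = c(5, 16),
                       mrcp_channels = c(11, 12, 19),
                       mrcp_amplitude_uV = 100,
                       erd_channels = c(11, 12, 19, 20), erd_depth = 0.5,
                       ers_channels = c(11, 19), ers_gain = 1,
                       noise_scale_uV = 40, noise_exponent = 2,
                       noise_knee_hz = 0.5,
                       lfb_rhythm_uV = 10, hfb_rhythm_uV = 3,
                       line_noise_uV = 0, line_freq_hz = 50,
                       saturation_uV = Inf, seed = 1) {
  cfg <- list(n_rows = n_rows, n_cols = n_cols, pitch_mm = pitch_mm, fs = fs,
              n_trials = n_trials, iti_range = iti_range,
              mrcp_channels = mrcp_channels,
              mrcp_amplitude_uV = mrcp_amplitude_uV,
              erd_channels = erd_channels, erd_depth = erd_depth,
              ers_channels = ers_channels, ers_gain = ers_gain,
              noise_scale_uV = noise_scale_uV,
              noise_exponent = noise_exponent, noise_knee_hz = noise_knee_hz,
              lfb_rhythm_uV = lfb_rhythm_uV, hfb_rhythm_uV = hfb_rhythm_uV,
              line_noise_uV = line_noise_uV, line_freq_hz = line_freq_hz,
              saturation_uV = saturation_uV, seed = seed)
  n_ch <- n_rows * n_cols
  bad <- setdiff(c(mrcp_channels, erd_channels, ers_channels), seq_len(n_ch))
  problems <- character(0)
  if (length(bad))
    problems <- c(problems, sprintf("effect channels outside 1..%d: %s",
                                    n_ch, paste(bad, collapse = ", ")))
  if (iti_range[1] <= 0 || iti_range[2] < iti_range[1])
    problems <- c(problems, "iti_range must satisfy 0 < lo <= hi")
  if (fs <= 0 || n_trials < 1)
    problems <- c(problems, "fs and n_trials must be positive")
  if (length(problems))
    stop_invalid(paste(problems, collapse = "; "),
                 "ecogmap_invalid_configuration")
  class(cfg) <- "sim_config"
  cfg
}

#' Canonical MRCP waveform
#'
#' Deterministic sum of smooth components over the epoch time axis: a
#' slow negative ramp building from `ramp_start_s` before onset (the
#' readiness potential), a sharp negative motor-potential peak at
#' `mp_latency_s` after onset, and a positive-going rebound, returning
#' to baseline. Band-limited well below 3 Hz by construction; only the
#' timing and band limitation are contractual, not biophysics.
#'
#' @param t time axis in seconds (0 = EMG onset).
#' @param amplitude_uV motor-potential peak magnitude (negative-going).
#' @param ramp_start_s readiness ramp start before onset (default 1.5 s).
#' @param ramp_frac ramp depth as a fraction of the peak (default 0.25).
#' @param mp_latency_s motor potential peak latency (default 0.1 s).
#' @param mp_sigma_s motor potential Gaussian width (default 0.1 s).
#' @param mrr_latency_s rebound latency (default 0.7 s).
#' @param mrr_sigma_s rebound width (default 0.25 s).
#' @param mrr_frac rebound amplitude fraction (default 0.4).
#' @return numeric vector over `t`, in microvolts.
#' @export
mrcp_waveform <- function(t, amplitude_uV = 100, ramp_start_s = 1.5,
                          ramp_frac = 0.25, mp_latency_s = 0.1,
                          mp_sigma_s = 0.1, mrr_latency_s = 0.7,
                          mrr_sigma_s = 0.25, mrr_frac = 0.4) {
  a <- amplitude_uV
  # readiness ramp: smooth rise over [-ramp_start, 0], smooth decay over
  # [0.2, 1.2] s
  up <- pmin(pmax((t + ramp_start_s) / ramp_start_s, 0), 1)
  up <- up^2 * (3 - 2 * up)
  down <- pmin(pmax((t - 0.2) / 1.0, 0), 1)
  down <- down^2 * (3 - 2 * down)
  ramp <- -ramp_frac * a * up * (1 - down)
  mp <- -a * exp(-(t - mp_latency_s)^2 / (2 * mp_sigma_s^2))
  mrr <- mrr_frac * a * exp(-(t - mrr_latency_s)^2 / (2 * mrr_sigma_s^2))
  ramp + mp + mrr
}

# amplitude-spectrum shape over the nfft FFT bins, symmetric in |f|,
# calibrated analytically so the synthesised time series has standard
# deviation sd_target
noise_shape <- function(nfft, fs, sd_target, exponent = 2, knee_hz = 0.5,
                        band = NULL) {
  f <- c(0, seq_len(nfft / 2), seq(nfft / 2 - 1, 1)) * fs / nfft
  if (!is.null(band)) {
    shape <- as.numeric(f >= band[1] & f <= band[2])
  } else {
    shape <- 1 / pmax(f, knee_hz)^(exponent / 2)
    shape[1] <- 0  # no DC
  }
  norm <- sqrt(sum(shape^2))
  if (norm == 0) return(shape)
  shape * (sd_target * nfft / norm)
}

# two independent real noises with the given amplitude-spectrum shape,
# from a single complex FFT (real and imaginary parts of the inverse
# transform of non-Hermitian complex white noise are independent)
shaped_noise_pair <- function(n, shape) {
  nfft <- length(shape)
  z <- complex(real = stats::rnorm(nfft), imaginary = stats::rnorm(nfft))
  y <- fft(z * shape, inverse = TRUE) / nfft
  list(Re(y)[seq_len(n)], Im(y)[seq_len(n)])
}

# single realisation (first of a pair); kept for unit-level use
shaped_noise <- function(n, fs, scale, exponent = 2, knee_hz = 0.5,
                         band = NULL) {
  nfft <- stats::nextn(n, 2)
  shape <- noise_shape(nfft, fs, scale, exponent, knee_hz, band)
  shaped_noise_pair(n, shape)[[1]]
}

# smooth 0->1->0 gate over [0, dur] seconds with cosine ramps
task_gate <- function(t, dur = 1, ramp = 0.1) {
  g <- rep(0, length(t))
  inside <- t >= 0 & t <= dur
  g[inside] <- 1
  rise <- t >= -ramp & t < 0
  g[rise] <- 0.5 * (1 - cos(pi * (t[rise] + ramp) / ramp))
  fall <- t > dur & t <= dur + ramp
  g[fall] <- 0.5 * (1 + cos(pi * (t[fall] - dur) / ramp))
  g
}

#' Simulate a full recording with ground truth
#'
#' Generates the continuous multichannel ECoG matrix, the EMG trace with
#' one burst per trial, the electrode geometry and a ground-truth object
#' (onset samples, per-channel effect labels, stimulation-positive set =
#' the MRCP cluster). Identical seeds give bit-identical output and the
#' caller's RNG state is untouched.
#'
#' @param cfg a [sim_config()].
#' @return list with `recording` (an [ecog_recording()]) and `truth`
#'   (class `sim_truth`: `onsets`, `labels`, `decs_positive`, `config`).
#' @export
simulate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    fs <- cfg$fs
    n_ch <- cfg$n_rows * cfg$n_cols
    itis <- stats::runif(cfg$n_trials - 1, cfg$iti_range[1], cfg$iti_range[2])
    onset_t <- 8 + c(0, cumsum(itis))        # seconds; generous lead-in
    total_s <- onset_t[length(onset_t)] + 6  # room for the post window
    n <- ceiling(total_s * fs)
    onsets <- round(onset_t * fs)            # 0-based onset samples
    tgrid <- (seq_len(n) - 1) / fs

    # per-trial jitter shared across channels (one cortical event)
    amp_jit <- stats::runif(cfg$n_trials, 0.8, 1.2)
    lat_jit <- stats::runif(cfg$n_trials, -0.025, 0.025)

    # evoked MRCP trace, reused on every MRCP channel
    evoked <- rep(0, n)
    win <- round(-2 * fs):round(4 * fs)  # relative samples with support
    for (k in seq_len(cfg$n_trials)) {
      idx <- onsets[k] + win + 1
      keep <- idx >= 1 & idx <= n
      tt <- win[keep] / fs - lat_jit[k]
      evoked[idx[keep]] <- evoked[idx[keep]] +
        amp_jit[k] * mrcp_waveform(tt, cfg$mrcp_amplitude_uV)
    }

    # modulation envelopes for the task second
    erd_env <- rep(1, n)
    ers_env <- rep(1, n)
    for (k in seq_len(cfg$n_trials)) {
      seg <- onsets[k] + seq(round(-0.2 * fs), round(1.4 * fs))
      keep <- seg >= 0 & seg < n
      tt <- (seg[keep] - onsets[k]) / fs
      g <- task_gate(tt, dur = 1, ramp = 0.1)
      erd_env[seg[keep] + 1] <- 1 - cfg$erd_depth * g
      ers_env[seg[keep] + 1] <- 1 + cfg$ers_gain * g
    }

    nfft <- stats::nextn(n, 2)
    bg_shape <- noise_shape(nfft, fs, cfg$noise_scale_uV, cfg$noise_exponent,
                            cfg$noise_knee_hz)
    mu_shape <- noise_shape(nfft, fs, cfg$lfb_rhythm_uV, band = c(8, 32))
    ga_shape <- noise_shape(nfft, fs, cfg$hfb_rhythm_uV, band = c(66, 90))
    # channels without a desynchronising rhythm draw background + mu/beta
    # rhythm from one combined spectrum (sum of independent Gaussian
    # processes); modulated components must stay separate
    static_shape <- sqrt(bg_shape^2 + mu_shape^2)

    data <- matrix(0, nrow = n_ch, ncol = n)
    is_erd <- seq_len(n_ch) %in% cfg$erd_channels
    is_ers <- seq_len(n_ch) %in% cfg$ers_channels
    # one complex FFT per component yields two independent realisations,
    # so process channels of the same composition in pairs
    for (type in unique(paste0(is_erd, is_ers))) {
      members <- which(paste0(is_erd, is_ers) == type)
      for (p in seq_len(ceiling(length(members) / 2))) {
        chs <- members[c(2 * p - 1, 2 * p)]
        chs <- chs[!is.na(chs)]
        erd_here <- is_erd[chs[1]]; ers_here <- is_ers[chs[1]]
        base <- if (erd_here) shaped_noise_pair(n, bg_shape)
                else shaped_noise_pair(n, static_shape)
        mu <- if (erd_here) shaped_noise_pair(n, mu_shape) else NULL
        ga <- if (ers_here) shaped_noise_pair(n, ga_shape) else NULL
        for (j in seq_along(chs)) {
          ch <- chs[j]
          x <- base[[j]]
          if (erd_here) x <- x + mu[[j]] * erd_env
          if (ers_here) x <- x + ga[[j]] * ers_env
          if (ch %in% cfg$mrcp_channels) x <- x + evoked
          if (cfg$line_noise_uV > 0)
            x <- x + cfg$line_noise_uV *
              sin(2 * pi * cfg$line_freq_hz * tgrid +
                    stats::runif(1, 0, 2 * pi))
          if (is.finite(cfg$saturation_uV))
            x <- pmin(pmax(x, -cfg$saturation_uV), cfg$saturation_uV)
          data[ch, ] <- x
        }
      }
    }

    # EMG: low noise floor plus a ~1 s burst from each onset
    emg <- stats::rnorm(n, sd = 0.02)
    for (k in seq_len(cfg$n_trials)) {
      seg <- onsets[k] + seq(0, round(1.1 * fs))
      keep <- seg >= 0 & seg < n
      tt <- (seg[keep] - onsets[k]) / fs
      env <- pmin(tt / 0.01, 1) * (1 - pmin(pmax((tt - 0.9) / 0.2, 0), 1))
      emg[seg[keep] + 1] <- emg[seg[keep] + 1] +
        env * stats::rnorm(sum(keep), sd = 0.4)
    }

    grid <- grid_layout(cfg$n_rows, cfg$n_cols, cfg$pitch_mm)
    labels <- rep("none", n_ch)
    labels[cfg$erd_channels] <- "erd"
    labels[cfg$ers_channels] <- ifelse(labels[cfg$ers_channels] == "erd",
                                       "erd+ers", "ers")
    labels[cfg$mrcp_channels] <- ifelse(labels[cfg$mrcp_channels] == "none",
                                        "mrcp",
                                        paste0("mrcp+",
                                               labels[cfg$mrcp_channels]))
    rec <- ecog_recording(data, fs, grid$channel, emg = emg, geometry = grid)
    truth <- structure(
      list(onsets = onsets,
           labels = setNames(labels, grid$channel),
           decs_positive = grid$channel[cfg$mrcp_channels],
           config = cfg),
      class = "sim_truth")
    list(recording = rec, truth = truth)
  })
}

#' Write a simulated recording as an on-disk fixture
#'
#' Produces `signals.edf` (ECoG channels plus a final `EMG` signal),
#' `events.csv` (trial_id, onset_sample), `geometry.csv` and
#' `truth.json` under `dir`.
#'
#' @param rec an [ecog_recording()].
#' @param truth a `sim_truth` object (or `NULL` to skip `truth.json`).
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths.
#' @export
write_fixture <- function(rec, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(edf = file.path(dir, "signals.edf"),
             events = file.path(dir, "events.csv"),
             geometry = file.path(dir, "geometry.csv"),
             truth = file.path(dir, "truth.json"))
  write_edf(rec, paths[["edf"]])
  write_events_csv(ecog_events(truth$onsets), paths[["events"]])
  write_geometry_csv(rec$geometry, paths[["geometry"]])
  jsonlite::write_json(
    list(onsets = truth$onsets,
         labels = as.list(truth$labels),
         decs_positive = truth$decs_positive,
         seed = truth$config$seed),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a fixture directory back
#' @param dir directory written by [write_fixture()].
#' @return list with `recording`, `events`, and (if present) `truth`.
#' @export
read_fixture <- function(dir) {
  rec <- read_edf(file.path(dir, "signals.edf"), emg_label = "EMG")
  rec$geometry <- read_geometry_csv(file.path(dir, "geometry.csv"))
  events <- read_events_csv(file.path(dir, "events.csv"))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  list(recording = rec, events = events, truth = truth)
}
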