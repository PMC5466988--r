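# In-code fixtures shared across test files. Everything is generated at
# test time; nothing binary lives in the repository.

# small, fast simulation for unit-level tests (not the acceptance world:
# fewer trials and tighter intervals keep the suite quick)
small_sim_config <- function(seed = 7, n_trials = 8, ...) {
  sim_config(n_rows = 2, n_cols = 4, n_trials = n_trials, iti_range = c(5, 6),
             mrcp_channels = 2, erd_channels = c(2, 3), ers_channels = 5,
             seed = seed, ...)
}

# hand-built trial set: nt trials x nch channels x time, values supplied
# by f(trial, channel) -> vector over the epoch
make_trialset <- function(nt, nch, fs = 100, pre_ms = 2000, post_ms = 4000,
                          f = function(ti, ch) rep(0, (pre_ms + post_ms) * fs / 1000)) {
  len <- (pre_ms + post_ms) * fs / 1000
  epochs <- array(0, dim = c(nt, nch, len),
                  dimnames = list(NULL, paste0("chan_", seq_len(nch)), NULL))
  for (ti in seq_len(nt))
    for (ch in seq_len(nch))
      epochs[ti, ch, ] <- f(ti, ch)
  structure(list(epochs = epochs, fs = fs,
                 window = c(pre_ms = pre_ms, post_ms = post_ms),
                 channel_ids = paste0("chan_", seq_len(nch)),
                 onsets = seq_len(nt) * 10 * fs,
                 keep = rep(TRUE, nt)),
            class = "ecog_trialset")
}

# independent oracle: signed squared point-biserial correlation between
# pooled values and the group label (population moments; textbook form,
# no shared code with the implementation under test)
signed_pb2 <- function(g1, g2) {
  x <- c(g1, g2)
  lab <- c(rep(1, length(g1)), rep(0, length(g2)))
  r <- sum((x - mean(x)) * (lab - mean(lab))) /
    sqrt(sum((x - mean(x))^2) * sum((lab - mean(lab))^2))
  sign(mean(g1) - mean(g2)) * r^2
}

# steady-state amplitude of a sinusoid-shaped response, measured away
# from the edges
mid_amplitude <- function(y, frac = 0.5) {
  n <- length(y)
  mid <- y[round(n * 0.25):round(n * 0.75)]
  (max(mid) - min(mid)) / 2
}
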