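# Template correlation scoring. Oracles: hand-evaluated Pearson r,
# signed squared point-biserial correlation for the R2 statistic, and
# the algebraic F relation for the ANOVA.

test_that("correlation coefficient: bounds, affine invariance, hand value", {
  set.seed(3)
  x <- rnorm(50)
  expect_equal(correlation_coefficient(x, x), 1)
  expect_equal(correlation_coefficient(x, -x), -1)
  expect_equal(correlation_coefficient(3 * x + 2, x), 1)
  # hand evaluation: x=(1,2,3), y=(1,2,4) -> 3 / sqrt(2 * 42/9)
  expect_equal(correlation_coefficient(c(1, 2, 3), c(1, 2, 4)),
               3 / sqrt(2 * 42 / 9), tolerance = 1e-12)
  expect_equal(round(correlation_coefficient(c(1, 2, 3), c(1, 2, 4)), 4),
               0.982)
  expect_warning(r <- correlation_coefficient(rep(1, 5), rnorm(5)),
                 class = "ecogmap_degenerate")
  expect_true(is.na(r))
  expect_error(correlation_coefficient(1:3, 1:4),
               class = "ecogmap_invalid_input")
})

test_that("signed R2 equals the signed squared point-biserial correlation", {
  expect_equal(signed_r2(c(0.3, 0.4), c(0.3, 0.4)), 0)
  # two constants, opposite groups: G = 0, R2 = 1, sign positive
  expect_equal(signed_r2(c(1, 1), c(-1, -1)), 1)
  expect_equal(signed_r2(c(-1, -1), c(1, 1)), -1)
  set.seed(4)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    q <- rnorm(n, mean = runif(1, -1, 1), sd = runif(1, 0.1, 2))
    t_ <- rnorm(n, mean = runif(1, -1, 1), sd = runif(1, 0.1, 2))
    expect_lt(abs(signed_r2(q, t_) - signed_pb2(q, t_)), 1e-10)
    # antisymmetry under group swap
    expect_lt(abs(signed_r2(t_, q) + signed_r2(q, t_)), 1e-12)
    expect_lte(abs(signed_r2(q, t_)), 1)
  }
})

test_that("ANOVA p, Bonferroni arithmetic and the F/R2 identity", {
  set.seed(5)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    q <- rnorm(n); t_ <- rnorm(n, mean = runif(1, -1, 1))
    sig <- channel_significance(q, t_, n_channels = 1)
    r2 <- abs(signed_r2(q, t_))
    expect_equal(sig$F, r2 / (1 - r2) * (2 * n - 2), tolerance = 1e-8)
    # agreement with R's reference ANOVA implementation
    p_ref <- stats::anova(stats::lm(y ~ g, data = data.frame(
      y = c(q, t_), g = factor(rep(1:2, each = n)))))[["Pr(>F)"]][1]
    expect_equal(sig$p_raw, p_ref, tolerance = 1e-10)
  }
  # corrected p: 0.0005 * 30 channels = 0.015 -> not significant at 0.01
  sig <- channel_significance(rnorm(20), rnorm(20), n_channels = 30)
  expect_equal(sig$p_corrected, min(1, sig$p_raw * 30))
  expect_false(min(1, 0.0005 * 30) < 0.01)
})

test_that("uncorrected type-I rate of the channel ANOVA is nominal", {
  set.seed(6)
  hits <- 0L
  nsim <- 1000
  for (i in seq_len(nsim)) {
    p <- channel_significance(rnorm(30), rnorm(30), n_channels = 1)$p_raw
    hits <- hits + (p < 0.05)
  }
  se <- sqrt(0.05 * 0.95 / nsim)
  expect_lt(abs(hits / nsim - 0.05), 2.5 * se + 1e-9)
})

test_that("grand average subtracts the pre-movement baseline", {
  w <- sin(seq(0, 4 * pi, length.out = 600)) + 2
  ts <- make_trialset(5, 2, f = function(ti, ch) w)
  ga <- grand_average(ts, "chan_1")
  # baseline window = first 400 ms of the 2000 ms pre-window at fs=100
  expect_equal(ga$waveform, w - mean(w[1:40]))
  expect_equal(ga$n_trials, 5L)

  # noisy trials converge to the baseline-corrected truth
  set.seed(8)
  tsn <- make_trialset(200, 1, f = function(ti, ch) w + rnorm(600, sd = 1))
  gan <- grand_average(tsn, 1)
  expect_lt(max(abs(gan$waveform - (w - mean(w[1:40])))), 3 * 1 / sqrt(200) * 4)

  ts1 <- make_trialset(1, 1, f = function(ti, ch) w)
  expect_equal(grand_average(ts1, 1)$waveform, w - mean(w[1:40]))
})

test_that("template building, representative choice and hold-out", {
  fs <- 100
  mk_ga <- function(w, ch = "chan_1")
    structure(list(waveform = w, baseline = 0, n_trials = 10, fs = fs,
                   window = c(pre_ms = 2000, post_ms = 4000), channel = ch),
              class = "ecog_grand_average")
  w <- cos(seq(0, 6 * pi, length.out = 600))
  tpl <- build_template(rep(list(mk_ga(w)), 5))
  # 0-500 ms post-onset segment: samples 201..250 at fs=100
  expect_length(tpl$waveform, 50)
  expect_equal(tpl$waveform, w[201:250])

  # fs=2000 -> 1000-sample template
  w2 <- rnorm(12000)
  ga2 <- structure(list(waveform = w2, baseline = 0, n_trials = 5, fs = 2000,
                        window = c(pre_ms = 2000, post_ms = 4000),
                        channel = "chan_9"), class = "ecog_grand_average")
  expect_length(build_template(list(ga2))$waveform, 1000)

  # opposite representatives cancel; the degenerate template errors downstream
  tpl0 <- build_template(list(mk_ga(w), mk_ga(-w)))
  ts <- make_trialset(4, 1, f = function(ti, ch) rnorm(600))
  expect_error(trial_ccs(ts, 1, tpl0), class = "ecogmap_degenerate")

  expect_error(build_template(list(mk_ga(w), ga2)),
               class = "ecogmap_invalid_input")

  # leave-one-out excludes exactly the held-out subject
  reps <- list(s1 = mk_ga(w), s2 = mk_ga(2 * w), s3 = mk_ga(3 * w))
  lo <- loso_template(reps, 3)
  expect_equal(lo$waveform, (w + 2 * w)[201:250] / 2)
  expect_equal(loso_template(reps, "s1")$waveform, (2.5 * w)[201:250])
  expect_error(loso_template(reps[1], 1), class = "ecogmap_invalid_input")
  # two subjects: the other subject's representative
  expect_equal(loso_template(reps[1:2], 1)$waveform, (2 * w)[201:250])

  # representative = channel with largest 0-500 ms peak; ties -> lowest index
  f <- function(ti, ch) {
    x <- rep(0, 600); x[210:230] <- -c(1, 2, 1, 3, 1)[ch]; x
  }
  ts5 <- make_trialset(3, 5, f = f)
  rep_ch <- select_representative(ts5)
  expect_equal(as.character(rep_ch), "chan_4")
  f2 <- function(ti, ch) { x <- rep(0, 600); x[220] <- -2; x }
  expect_equal(as.character(select_representative(make_trialset(2, 3, f = f2))),
               "chan_1")
  # pure noise: low-confidence flag below the floor
  set.seed(9)
  tsn <- make_trialset(3, 2, f = function(ti, ch) rnorm(600, sd = 0.1))
  expect_true(attr(select_representative(tsn, floor_uv = 5), "low_confidence"))
})

test_that("trial correlations are balanced and behave on known inputs", {
  fs <- 100
  tplw <- sin(seq(0, 2 * pi, length.out = 50))
  tpl <- structure(list(waveform = tplw, fs = fs, provenance = "x",
                        mean = mean(tplw)), class = "ecog_template")
  # every task segment equals the template -> q all 1
  f <- function(ti, ch) { x <- rnorm(600, sd = 0.2); x[201:250] <- tplw; x }
  set.seed(10)
  ts <- make_trialset(12, 1, f = f)
  cc <- trial_ccs(ts, 1, tpl)
  expect_length(cc$q, 12)
  expect_length(cc$t, 12)
  expect_true(all(cc$q > 0.999))

  # white-noise trials: both correlation sets near zero on average
  set.seed(11)
  tsn <- make_trialset(300, 1, f = function(ti, ch) rnorm(600))
  ccn <- trial_ccs(tsn, 1, tpl)
  se <- 1 / sqrt(50 - 3) / sqrt(300)  # Fisher-approx SE of a mean of r's
  expect_lt(abs(mean(ccn$q)), 4 * se)
  expect_lt(abs(mean(ccn$t)), 4 * se)

  # a degenerate (constant) trial is dropped from both vectors
  fdeg <- function(ti, ch) if (ti == 2) rep(1, 600) else rnorm(600)
  set.seed(12)
  tsd <- make_trialset(5, 1, f = fdeg)
  expect_message(ccd <- trial_ccs(tsd, 1, tpl), "dropped 1")
  expect_length(ccd$q, 4)
  expect_equal(ccd$n_dropped, 1L)
})

test_that("etam_map flags the embedded-MRCP channel and signs R2 positive", {
  set.seed(13)
  fs <- 100
  mrcp <- -exp(-((seq(0, 0.5, length.out = 50) - 0.25)^2) / 0.01)
  f <- function(ti, ch) {
    x <- rnorm(600, sd = 0.3)
    if (ch == 2) x[201:250] <- x[201:250] + 3 * mrcp
    x
  }
  ts <- make_trialset(30, 4, f = f)
  tpl <- structure(list(waveform = mrcp, fs = fs, provenance = "sim",
                        mean = mean(mrcp)), class = "ecog_template")
  sc <- etam_map(ts, tpl)
  expect_s3_class(sc, "etam_scores")
  expect_identical(sc$channel[sc$significant], "chan_2")
  # the negative-going potential scores a positive R2
  expect_gt(sc$r2[sc$channel == "chan_2"], 0)
  # Bonferroni factor is the analysed channel count
  expect_equal(sc$p_corrected, pmin(1, sc$p_raw * 4))
})
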