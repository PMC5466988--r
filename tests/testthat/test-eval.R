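# Ground-truth geometry, confusion statistics and topographic maps.
# The chi-square implementation is cross-checked against R's reference
# chisq.test (Yates correction) as the independent oracle.

test_that("stimulation-positive electrodes follow the 6 mm circle rule", {
  g <- grid_layout(2, 4, pitch_mm = 10)
  # site exactly on an electrode centre: only that electrode (next one
  # is 10 mm > 6 mm away)
  hit <- decs_positive_electrodes(g, data.frame(x_mm = 10, y_mm = 0))
  expect_identical(hit, "chan_2")
  # site midway between two neighbours (5 mm each): both included
  hit2 <- decs_positive_electrodes(g, data.frame(x_mm = 5, y_mm = 0))
  expect_setequal(hit2, c("chan_1", "chan_2"))
  # union over sites; empty set allowed
  hit3 <- decs_positive_electrodes(g, data.frame(x_mm = c(0, 100),
                                                 y_mm = c(0, 100)))
  expect_identical(hit3, "chan_1")
  expect_length(decs_positive_electrodes(g, data.frame(x_mm = 50, y_mm = 50)),
                0)
  expect_error(decs_positive_electrodes(g, data.frame()[0, ]),
               class = "ecogmap_invalid_input")
})

test_that("confusion counts and margins behave on constructed sets", {
  all_el <- paste0("e", 1:205)
  test_pos <- paste0("e", 1:18)
  truth_pos <- paste0("e", c(1:9, 101, 102))  # 11 positives, 9 overlapping
  cc <- confusion_counts(test_pos, truth_pos, all_el)
  expect_equal(unlist(cc[c("A", "B", "C", "D")]),
               c(A = 9, B = 9, C = 2, D = 185))
  # marginal identities
  expect_equal(cc$A + cc$C, length(truth_pos))
  expect_equal(cc$A + cc$B + cc$C + cc$D, length(all_el))

  ident <- confusion_counts(truth_pos, truth_pos, all_el)
  expect_equal(ident$B + ident$C, 0)
  disj <- confusion_counts("e200", truth_pos, all_el)
  expect_equal(disj$A, 0)
  expect_error(confusion_counts("zz", truth_pos, all_el),
               class = "ecogmap_invalid_input")
})

test_that("sensitivity/specificity formulae and undefined margins", {
  cc <- structure(list(A = 9, B = 9, C = 2, D = 185),
                  class = "confusion_counts")
  ss <- sensitivity_specificity(cc)
  expect_equal(unname(ss), c(100 * 9 / 11, 100 * 185 / 194))
  # swapping test and truth swaps B and C
  sw <- structure(list(A = 9, B = 2, C = 9, D = 185),
                  class = "confusion_counts")
  ss2 <- sensitivity_specificity(sw)
  expect_equal(ss2[["sensitivity"]], 100 * 9 / 18)
  cc0 <- structure(list(A = 0, B = 3, C = 0, D = 5),
                   class = "confusion_counts")
  expect_error(sensitivity_specificity(cc0),
               class = "ecogmap_undefined_metric")
})

test_that("Yates chi-square matches the reference implementation", {
  set.seed(30)
  for (i in 1:50) {
    tab <- matrix(sample(1:60, 4, replace = TRUE), 2)
    cc <- structure(list(A = tab[1, 1], B = tab[1, 2],
                         C = tab[2, 1], D = tab[2, 2]),
                    class = "confusion_counts")
    ours <- chi_square_independence(cc, yates = TRUE)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-12)
    # the continuity correction never increases the statistic
    unc <- chi_square_independence(cc, yates = FALSE)
    expect_lte(ours$chi2, unc$chi2 + 1e-12)
  }
  # counts proportional to the margins: independence, uncorrected 0
  cc_ind <- structure(list(A = 10, B = 20, C = 30, D = 60),
                      class = "confusion_counts")
  expect_equal(chi_square_independence(cc_ind, yates = FALSE)$chi2, 0)
  cc_zero <- structure(list(A = 0, B = 0, C = 3, D = 5),
                       class = "confusion_counts")
  expect_error(chi_square_independence(cc_zero),
               class = "ecogmap_invalid_input")
})

test_that("activation raster: support, linearity, disjoint kernels", {
  g <- grid_layout(1, 2, pitch_mm = 40)
  zero <- activation_map(g, c(chan_1 = 0, chan_2 = 0))
  expect_true(all(zero$values == 0))

  one <- activation_map(g, c(chan_1 = 1), resolution_mm = 0.5)
  peak <- which(one$values == max(one$values), arr.ind = TRUE)
  expect_equal(one$x_mm[peak[1, 2]], 0)
  expect_equal(one$y_mm[peak[1, 1]], 0)
  # support truncated at the 12.5 mm kernel radius
  d2 <- outer((one$y_mm - 0)^2, (one$x_mm - 0)^2, `+`)
  expect_true(all(one$values[d2 > 12.5^2 + 1e-9] == 0))
  expect_true(all(one$values[d2 < 12.4^2] > 0))

  # linearity: raster of (w1, w2) = w1 * k1 + w2 * k2; integral scales
  two <- activation_map(g, c(chan_1 = 2, chan_2 = -1))
  k2 <- activation_map(g, c(chan_2 = 1))
  expect_equal(two$values, 2 * one$values - 1 * k2$values)
  expect_equal(sum(two$values), (2 - 1) * sum(one$values), tolerance = 1e-9)

  # 40 mm apart with 25 mm support: two disjoint bumps
  expect_true(any(one$values > 0 & k2$values == 0))
  expect_false(any(one$values > 0 & k2$values > 0))
})

test_that("risk partition splits electrodes three ways and conserves them", {
  et <- c(a = TRUE, b = TRUE, c = FALSE, d = FALSE)
  ef <- c(a = TRUE, b = FALSE, c = TRUE, d = FALSE)
  p <- site_risk_partition(et, ef)
  expect_identical(p$functional_convinced, "a")
  expect_setequal(p$functional_high_risk, c("b", "c"))
  expect_identical(p$negative, "d")
  expect_setequal(unlist(p), names(et))
  expect_error(site_risk_partition(et, ef[1:3]),
               class = "ecogmap_invalid_input")
})

test_that("grid constructor enforces distinct, separated contacts", {
  expect_error(electrode_grid(c("a", "a"), c(0, 10), c(0, 0)),
               class = "ecogmap_invalid_input")
  expect_error(electrode_grid(c("a", "b"), c(0, 1), c(0, 0)),
               class = "ecogmap_invalid_input")
  g <- grid_layout(4, 8)
  expect_equal(nrow(g), 32)
  expect_equal(g$x_mm[2] - g$x_mm[1], 10)
})
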