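# Configuration validation and the end-to-end drivers on a small
# simulated fixture.

test_that("run_config validates every offending parameter at once", {
  expect_s3_class(run_config(), "run_config")
  err <- tryCatch(run_config(low_hz = -1, alpha = 2, efam_pre_ms = 1000),
                  error = identity)
  expect_s3_class(err, "ecogmap_invalid_configuration")
  expect_match(conditionMessage(err), "low_hz")
  expect_match(conditionMessage(err), "alpha")
  expect_match(conditionMessage(err), "efam_pre_ms")
  expect_error(run_config(edf = "no/such/file.edf"),
               class = "ecogmap_invalid_configuration")
  # Nyquist check happens against the recording
  expect_error(ecogmap:::check_config_against_fs(run_config(high_hz = 900),
                                                 fs = 1000),
               class = "ecogmap_invalid_configuration")
})

test_that("run_etam / run_efam produce parseable, deterministic reports", {
  dir <- withr::local_tempdir()
  out <- simulate_recording(small_sim_config(seed = 55))
  paths <- write_fixture(out$recording, out$truth, file.path(dir, "fix"))

  cfg <- run_config(edf = paths[["edf"]], events = paths[["events"]],
                    geometry = paths[["geometry"]],
                    out_dir = file.path(dir, "run1"))
  sc <- run_etam(cfg)
  expect_true(file.exists(file.path(dir, "run1", "etam_scores.csv")))
  expect_true(file.exists(file.path(dir, "run1", "etam_raster.txt")))
  man <- jsonlite::read_json(file.path(dir, "run1", "manifest.json"))
  expect_identical(man$stage, "etam")
  expect_true(all(c("seed", "parameters", "input_digests") %in% names(man)))
  tab <- read.csv(file.path(dir, "run1", "etam_scores.csv"))
  expect_identical(nrow(tab), 8L)

  # identical config -> identical score table
  cfg2 <- run_config(edf = paths[["edf"]], events = paths[["events"]],
                     geometry = paths[["geometry"]],
                     out_dir = file.path(dir, "run2"))
  run_etam(cfg2)
  expect_identical(readLines(file.path(dir, "run1", "etam_scores.csv")),
                   readLines(file.path(dir, "run2", "etam_scores.csv")))

  ef <- run_efam(run_config(edf = paths[["edf"]], events = paths[["events"]],
                            out_dir = file.path(dir, "run3")))
  expect_true(file.exists(file.path(dir, "run3", "efam_scores.csv")))
  expect_identical(nrow(as.data.frame(ef)), 16L)  # 8 channels x 2 bands
})

test_that("run_eval reproduces a hand-computed confusion table", {
  dir <- withr::local_tempdir()
  grid <- grid_layout(2, 4)
  write_geometry_csv(grid, file.path(dir, "geometry.csv"))
  # stimulation sites on top of chan_2 and chan_3
  write.csv(data.frame(site_id = 1:2, x_mm = c(10, 20), y_mm = c(0, 0),
                       response_label = c("hand", "hand")),
            file.path(dir, "sites.csv"), row.names = FALSE)
  etam_scores <- data.frame(channel = grid$channel,
                            significant = grid$channel %in%
                              c("chan_2", "chan_5"))
  efam_scores <- data.frame(channel = rep(grid$channel, 2),
                            band = rep(c("LFB", "HFB"), each = 8),
                            significant = rep(grid$channel, 2) %in% "chan_2")
  cfg <- run_config(geometry = file.path(dir, "geometry.csv"),
                    stim_sites = file.path(dir, "sites.csv"),
                    out_dir = file.path(dir, "eval"))
  rep <- run_eval(cfg, etam_scores, efam_scores)
  # truth = {chan_2, chan_3}; ETAM+ = {chan_2, chan_5}
  expect_equal(rep$etam$A, 1); expect_equal(rep$etam$B, 1)
  expect_equal(rep$etam$C, 1); expect_equal(rep$etam$D, 5)
  expect_equal(rep$etam$sensitivity, 50)
  expect_equal(rep$etam$specificity, 100 * 5 / 6)
  # partition: convinced chan_2; high-risk chan_5; 8 electrodes conserved
  expect_identical(rep$risk_partition$functional_convinced, "chan_2")
  expect_identical(rep$risk_partition$functional_high_risk, "chan_5")
  expect_length(unlist(rep$risk_partition), 8L)
  expect_true(file.exists(file.path(dir, "eval", "eval_report.json")))

  # empty truth set surfaces as an undefined-metric error, not NaN
  write.csv(data.frame(site_id = 1, x_mm = 500, y_mm = 500,
                       response_label = "hand"),
            file.path(dir, "far.csv"), row.names = FALSE)
  cfg2 <- run_config(geometry = file.path(dir, "geometry.csv"),
                     stim_sites = file.path(dir, "far.csv"),
                     out_dir = file.path(dir, "eval2"))
  expect_error(run_eval(cfg2, etam_scores),
               class = "ecogmap_undefined_metric")
})

test_that("the CLI front end validates and exits with the documented codes", {
  cli <- system.file("cli.R", package = "ecogmap")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  # bad subcommand -> 2
  expect_equal(suppressWarnings(
    system2(rscript, c(cli, "frobnicate"), stdout = FALSE, stderr = FALSE)),
    2L)
  # missing input file -> validation error, exit 2, no partial outputs
  dir <- withr::local_tempdir()
  code <- suppressWarnings(
    system2(rscript, c(cli, "etam", "--edf", "missing.edf",
                       "--events", "missing.csv",
                       "--out", file.path(dir, "o")),
            stdout = FALSE, stderr = FALSE))
  expect_equal(code, 2L)
  expect_false(file.exists(file.path(dir, "o", "etam_scores.csv")))
})
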