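# Reproducible end-to-end runs: validated configuration, pipeline
# drivers, run manifests. The command-line front end (inst/cli.R) is a
# thin wrapper over these functions.

#' Run configuration with validated analysis parameters
#'
#' Every analysis parameter of the pipeline, defaulting to the standard
#' protocol values: 0.05-3 Hz order-2 band-pass; epochs -2000/+4000 ms
#' (temporal map) and -3500/+4000 ms (spectral map); baseline first
#' 400 ms; task 0-500 ms and rest -2000..-1500 ms correlation windows;
#' spectral task 0-1000 ms and rest -3500..-2500 ms; LFB 8-32 Hz and HFB
#' 66-90 Hz; corrected alpha 0.01; 6 mm stimulation-site radius; 25 mm /
#' sigma 0.4 map kernel. Validation reports every violated parameter at
#' once before any computation.
#'
#' @param edf,events,geometry,stim_sites input file paths (optional
#'   depending on the driver used).
#' @param out_dir output directory.
#' @param low_hz,high_hz,filter_order band-pass settings.
#' @param pre_ms,post_ms temporal-map epoch window (ms).
#' @param efam_pre_ms spectral-map pre-window (ms, >= 3500).
#' @param lfb,hfb analysis bands `c(lo, hi)` in Hz.
#' @param alpha Bonferroni-corrected significance level.
#' @param amplitude_z_max trial-rejection robust z threshold.
#' @param decs_radius_mm stimulation-positive inclusion radius.
#' @param kernel_diameter_mm,kernel_sigma_rel,raster_resolution_mm
#'   activation-map kernel settings.
#' @param seed integer seed for any stochastic stage.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(edf = NULL, events = NULL, geometry = NULL,
                       stim_sites = NULL, out_dir = tempfile("ecogmap_run_"),
                       low_hz = 0.05, high_hz = 3, filter_order = 2,
                       pre_ms = 2000, post_ms = 4000, efam_pre_ms = 3500,
                       lfb = c(8, 32), hfb = c(66, 90), alpha = 0.01,
                       amplitude_z_max = 5, decs_radius_mm = 6,
                       kernel_diameter_mm = 25, kernel_sigma_rel = 0.4,
                       raster_resolution_mm = 0.5, seed = 1) {
  cfg <- as.list(environment())
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(low_hz > 0 && high_hz > low_hz, "need 0 < low_hz < high_hz")
  chk(filter_order >= 1, "filter_order must be >= 1")
  chk(pre_ms >= 2000, "pre_ms must cover the -2000 ms rest window")
  chk(post_ms >= 1000, "post_ms must cover the task windows")
  chk(efam_pre_ms >= 3500, "efam_pre_ms must cover the -3500 ms rest window")
  chk(length(lfb) == 2 && lfb[1] < lfb[2], "lfb must be c(lo, hi), lo < hi")
  chk(length(hfb) == 2 && hfb[1] < hfb[2], "hfb must be c(lo, hi), lo < hi")
  chk(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  chk(amplitude_z_max > 0, "amplitude_z_max must be positive")
  chk(decs_radius_mm > 0, "decs_radius_mm must be positive")
  chk(kernel_diameter_mm > 0 && kernel_sigma_rel > 0 &&
        raster_resolution_mm > 0, "kernel settings must be positive")
  for (p in c("edf", "events", "geometry", "stim_sites")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      problems <- c(problems, sprintf("%s: file not found: %s", p, cfg[[p]]))
  }
  if (length(problems))
    stop_invalid(paste0("invalid configuration:\n  - ",
                        paste(problems, collapse = "\n  - ")),
                 "ecogmap_invalid_configuration")
  class(cfg) <- "run_config"
  cfg
}

# validation at Nyquist needs the sampling rate, known only once the
# recording is loaded
check_config_against_fs <- function(cfg, fs) {
  problems <- character(0)
  if (cfg$high_hz >= fs / 2)
    problems <- c(problems,
                  sprintf("high_hz = %g must be below Nyquist (%g)",
                          cfg$high_hz, fs / 2))
  if (cfg$hfb[2] > fs / 2)
    problems <- c(problems, "hfb upper edge above Nyquist")
  if (length(problems))
    stop_invalid(paste0("invalid configuration:\n  - ",
                        paste(problems, collapse = "\n  - ")),
                 "ecogmap_invalid_configuration")
  invisible(cfg)
}

write_manifest <- function(cfg, out_dir, stage, inputs = character()) {
  digests <- lapply(inputs[file.exists(inputs)], function(p)
    as.character(tools::md5sum(p)))
  jsonlite::write_json(
    list(stage = stage,
         package_version = as.character(utils::packageVersion("ecogmap")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), tz = "UTC"),
         seed = cfg$seed,
         parameters = cfg[setdiff(names(cfg), "out_dir")],
         input_digests = digests),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null", force = TRUE)
}

# shared front half: load inputs, CAR, return recording + events
load_inputs <- function(cfg) {
  if (is.null(cfg$edf) || is.null(cfg$events))
    stop_invalid("edf and events inputs are required",
                 "ecogmap_io_error")
  rec <- read_edf(cfg$edf)
  if (!is.null(cfg$geometry)) rec$geometry <- read_geometry_csv(cfg$geometry)
  check_config_against_fs(cfg, rec$fs)
  events <- read_events_csv(cfg$events)
  list(rec = rec, events = events)
}

#' Run the temporal (MRCP template) mapping pipeline
#'
#' Loads the recording, applies the common average reference and the
#' MRCP band-pass, epochs around the events, screens trials, builds the
#' template from the recording's own representative channel (or uses
#' `template` when supplied), maps every channel and writes
#' `etam_scores.csv`, `etam_significant.txt`, `etam_raster.txt` and
#' `manifest.json` into `cfg$out_dir`.
#'
#' @param cfg a [run_config()] with `edf` and `events` set.
#' @param template optional `ecog_template` (e.g. cross-validated).
#' @return the `etam_scores` data frame, invisibly; side effect: report
#'   files.
#' @export
run_etam <- function(cfg, template = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  io <- load_inputs(cfg)
  rec <- bandpass_mrcp(apply_car(io$rec), cfg$low_hz, cfg$high_hz,
                       cfg$filter_order)
  ts <- epoch_trials(rec, io$events, cfg$pre_ms, cfg$post_ms)
  ts <- reject_trials(ts, cfg$amplitude_z_max)
  if (is.null(template)) {
    rep_ch <- select_representative(ts)
    template <- build_template(list(grand_average(ts, rep_ch)))
  }
  scores <- etam_map(ts, template, alpha = cfg$alpha)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(scores), file.path(cfg$out_dir, "etam_scores.csv"),
            row.names = FALSE)
  writeLines(scores$channel[scores$significant],
             file.path(cfg$out_dir, "etam_significant.txt"))
  if (!is.null(rec$geometry)) {
    w <- ifelse(scores$significant, scores$r2, 0)
    names(w) <- scores$channel
    raster <- activation_map(rec$geometry, w, cfg$raster_resolution_mm,
                             cfg$kernel_diameter_mm, cfg$kernel_sigma_rel)
    write_raster(raster, file.path(cfg$out_dir, "etam_raster.txt"))
  }
  write_manifest(cfg, cfg$out_dir, "etam",
                 unlist(cfg[c("edf", "events", "geometry")]))
  invisible(scores)
}

#' Run the spectral mapping pipeline
#'
#' Same front end as [run_etam()] but without the MRCP band-pass
#' (spectra need the full bandwidth); epochs with the longer spectral
#' pre-window and writes `efam_scores.csv` and `efam_significant.txt`.
#'
#' @param cfg a [run_config()].
#' @return the `efam_scores` data frame, invisibly.
#' @export
run_efam <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  io <- load_inputs(cfg)
  rec <- apply_car(io$rec)
  ts <- epoch_trials(rec, io$events, cfg$efam_pre_ms, cfg$post_ms)
  ts <- reject_trials(ts, cfg$amplitude_z_max)
  scores <- efam_map(ts, bands = list(LFB = cfg$lfb, HFB = cfg$hfb),
                     alpha = cfg$alpha)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(scores), file.path(cfg$out_dir, "efam_scores.csv"),
            row.names = FALSE)
  writeLines(efam_positive(scores),
             file.path(cfg$out_dir, "efam_significant.txt"))
  write_manifest(cfg, cfg$out_dir, "efam",
                 unlist(cfg[c("edf", "events", "geometry")]))
  invisible(scores)
}

#' Evaluate mapping results against stimulation ground truth
#'
#' Reads score tables (as written by [run_etam()] / [run_efam()]), the
#' grid geometry and the stimulation-site CSV (`site_id, x_mm, y_mm`,
#' optional `response_label`); computes confusion counts,
#' sensitivity/specificity, the Yates chi-square and the clinical risk
#' partition, and writes `eval_report.json` + `eval_report.csv`.
#'
#' @param cfg a [run_config()] with `geometry` and `stim_sites` set.
#' @param etam_scores,efam_scores score data frames or paths to their
#'   CSVs.
#' @return the report list, invisibly.
#' @export
run_eval <- function(cfg, etam_scores, efam_scores = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (missing(etam_scores) || is.null(etam_scores))
    stop_invalid("etam_scores input is required", "ecogmap_io_error")
  if (is.character(etam_scores)) etam_scores <- read.csv(etam_scores)
  if (is.character(efam_scores)) efam_scores <- read.csv(efam_scores)
  if (is.null(cfg$geometry) || is.null(cfg$stim_sites))
    stop_invalid("geometry and stim_sites inputs are required",
                 "ecogmap_io_error")
  grid <- read_geometry_csv(cfg$geometry)
  sites <- read.csv(cfg$stim_sites)
  if ("response_label" %in% names(sites))
    sites <- sites[sites$response_label != "negative", , drop = FALSE]
  truth <- decs_positive_electrodes(grid, sites, cfg$decs_radius_mm)
  if (!length(truth))
    stop_invalid("no stimulation-positive electrode: metrics undefined",
                 "ecogmap_undefined_metric")
  all_el <- etam_scores$channel
  report <- list()
  per_method <- function(pos, name) {
    cc <- confusion_counts(pos, truth, all_el)
    ss <- sensitivity_specificity(cc)
    ch <- chi_square_independence(cc)
    list(method = name, A = cc$A, B = cc$B, C = cc$C, D = cc$D,
         sensitivity = ss[["sensitivity"]], specificity = ss[["specificity"]],
         chi2 = ch$chi2, p = ch$p)
  }
  etam_pos <- etam_scores$channel[etam_scores$significant]
  report$etam <- per_method(etam_pos, "etam")
  if (!is.null(efam_scores)) {
    efam_pos <- unique(efam_scores$channel[efam_scores$significant])
    report$efam <- per_method(efam_pos, "efam")
    for (bn in unique(efam_scores$band)) {
      sub <- efam_scores[efam_scores$band == bn, ]
      report[[tolower(bn)]] <-
        per_method(sub$channel[sub$significant], tolower(bn))
    }
    part <- site_risk_partition(
      setNames(all_el %in% etam_pos, all_el),
      setNames(all_el %in% efam_pos, all_el))
    report$risk_partition <- part
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, file.path(cfg$out_dir, "eval_report.json"),
                       auto_unbox = TRUE, digits = NA)
  tab <- do.call(rbind, lapply(report[!names(report) %in% "risk_partition"],
                               as.data.frame))
  write.csv(tab, file.path(cfg$out_dir, "eval_report.csv"), row.names = FALSE)
  write_manifest(cfg, cfg$out_dir, "eval",
                 unlist(cfg[c("geometry", "stim_sites")]))
  invisible(report)
}

#' Map a recording in memory
#'
#' Functional core of [run_etam()] / [run_efam()] without file I/O: takes
#' a loaded recording and its events, applies the common average
#' reference, runs the spectral map on the broadband data and the
#' temporal map on the 0.05-3 Hz band-passed data, and returns both
#' score tables plus the template used.
#'
#' @param rec an [ecog_recording()].
#' @param events an [ecog_events()].
#' @param cfg a [run_config()] providing the analysis parameters.
#' @param template optional `ecog_template`; by default the recording's
#'   own representative channel provides it.
#' @param methods subset of `c("etam", "efam")`.
#' @return list with elements `etam`, `efam` (score data frames or
#'   `NULL`) and `template`.
#' @export
map_recording <- function(rec, events, cfg = run_config(),
                          template = NULL, methods = c("etam", "efam")) {
  stopifnot(inherits(rec, "ecog_recording"), inherits(events, "ecog_events"))
  check_config_against_fs(cfg, rec$fs)
  rec <- apply_car(rec)
  out <- list(etam = NULL, efam = NULL, template = template)
  if ("efam" %in% methods) {
    ts2 <- reject_trials(epoch_trials(rec, events, cfg$efam_pre_ms, 1000),
                         cfg$amplitude_z_max)
    out$efam <- efam_map(ts2, bands = list(LFB = cfg$lfb, HFB = cfg$hfb),
                         alpha = cfg$alpha)
    rm(ts2)
  }
  if ("etam" %in% methods) {
    rec <- bandpass_mrcp(rec, cfg$low_hz, cfg$high_hz, cfg$filter_order)
    ts <- reject_trials(epoch_trials(rec, events, cfg$pre_ms, cfg$post_ms),
                        cfg$amplitude_z_max)
    rm(rec)
    if (is.null(template)) {
      rep_ch <- select_representative(ts)
      template <- build_template(list(grand_average(ts, rep_ch)))
    }
    out$etam <- etam_map(ts, template, alpha = cfg$alpha)
    out$template <- template
  }
  out
}

#' Simulate and write a fixture in one call
#'
#' @param cfg a [run_config()] (only `out_dir` and `seed` are used).
#' @param sim a [sim_config()]; its seed defaults to `cfg$seed`.
#' @return the written paths, invisibly.
#' @export
run_simulate <- function(cfg, sim = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(sim)) sim <- sim_config(seed = cfg$seed)
  out <- simulate_recording(sim)
  paths <- write_fixture(out$recording, out$truth, cfg$out_dir)
  write_manifest(cfg, cfg$out_dir, "simulate")
  invisible(paths)
}
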