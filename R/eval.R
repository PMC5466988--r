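# Evaluation against stimulation ground truth: electrode geometry,
# confusion counts, sensitivity/specificity, Yates chi-square, Gaussian
# kernel topographic maps and the clinical risk partition.

#' Electrode grid geometry
#'
#' Per-channel planar coordinates in millimetres. The clinical arrays
#' are 4 mm diameter contacts at 10 mm pitch in 4 x 8 / 6 x 8 layouts or
#' strips.
#'
#' @param channel channel labels.
#' @param x_mm,y_mm coordinates in mm.
#' @param electrode_diameter_mm contact diameter (default 4).
#' @param pitch_mm nominal inter-electrode distance (default 10).
#' @return a `data.frame` of class `electrode_grid`.
#' @export
electrode_grid <- function(channel, x_mm, y_mm, electrode_diameter_mm = 4,
                           pitch_mm = 10) {
  channel <- as.character(channel)
  if (anyDuplicated(channel))
    stop_invalid("duplicate channel labels in grid", "ecogmap_invalid_input")
  if (length(x_mm) != length(channel) || length(y_mm) != length(channel))
    stop_invalid("coordinate vectors must match channel labels",
                 "ecogmap_invalid_input")
  if (anyDuplicated(cbind(x_mm, y_mm)))
    stop_invalid("electrode coordinates must be unique",
                 "ecogmap_invalid_input")
  d <- as.matrix(stats::dist(cbind(x_mm, y_mm)))
  diag(d) <- Inf
  if (any(d < electrode_diameter_mm))
    stop_invalid("electrodes closer than one contact diameter",
                 "ecogmap_invalid_input")
  structure(data.frame(channel = channel, x_mm = x_mm, y_mm = y_mm),
            electrode_diameter_mm = electrode_diameter_mm,
            pitch_mm = pitch_mm,
            class = c("electrode_grid", "data.frame"))
}

#' Regular rows x cols grid at fixed pitch
#' @param rows,cols layout dimensions.
#' @param pitch_mm inter-electrode distance in mm.
#' @param prefix channel label prefix.
#' @return an [electrode_grid()] in row-major channel order.
#' @export
grid_layout <- function(rows, cols, pitch_mm = 10, prefix = "chan_") {
  idx <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  electrode_grid(paste0(prefix, seq_len(rows * cols)),
                 x_mm = (idx$col - 1) * pitch_mm,
                 y_mm = (idx$row - 1) * pitch_mm,
                 pitch_mm = pitch_mm)
}

#' Read / write grid geometry CSV (channel_id, x_mm, y_mm)
#' @param path CSV path.
#' @return an [electrode_grid()].
#' @export
read_geometry_csv <- function(path) {
  df <- read.csv(path)
  nm <- if ("channel_id" %in% names(df)) "channel_id" else "channel"
  electrode_grid(df[[nm]], df$x_mm, df$y_mm)
}

#' @rdname read_geometry_csv
#' @param grid an [electrode_grid()].
#' @export
write_geometry_csv <- function(grid, path) {
  write.csv(data.frame(channel_id = grid$channel, x_mm = grid$x_mm,
                       y_mm = grid$y_mm), path, row.names = FALSE)
  invisible(path)
}

#' Electrodes counted as stimulation-positive
#'
#' An electrode is stimulation-positive when its centre lies within
#' `radius_mm` (default 6 mm) of any positive stimulation site; the
#' union over sites is returned.
#'
#' @param grid an [electrode_grid()].
#' @param stim_sites data frame (or matrix) with `x_mm`, `y_mm` columns.
#' @param radius_mm inclusion radius in mm.
#' @return character vector of positive electrode labels (may be empty).
#' @export
decs_positive_electrodes <- function(grid, stim_sites, radius_mm = 6) {
  if (is.null(dim(stim_sites)))
    stop_invalid("stim_sites must have x_mm / y_mm columns",
                 "ecogmap_invalid_input")
  stim_sites <- as.data.frame(stim_sites)
  if (!nrow(stim_sites))
    stop_invalid("need at least one stimulation site", "ecogmap_invalid_input")
  hit <- rep(FALSE, nrow(grid))
  for (i in seq_len(nrow(stim_sites))) {
    d2 <- (grid$x_mm - stim_sites$x_mm[i])^2 +
          (grid$y_mm - stim_sites$y_mm[i])^2
    hit <- hit | d2 <= radius_mm^2
  }
  grid$channel[hit]
}

#' Confusion counts of a test map against ground truth
#'
#' The 2 x 2 table: `A` true positives, `B` false positives, `C` false
#' negatives, `D` true negatives, over the analysed electrode set.
#'
#' @param test_pos electrodes flagged by the mapping method.
#' @param truth_pos stimulation-positive electrodes.
#' @param all_electrodes every analysed electrode.
#' @return list of class `confusion_counts` with fields `A`, `B`, `C`, `D`.
#' @export
confusion_counts <- function(test_pos, truth_pos, all_electrodes) {
  test_pos <- unique(as.character(test_pos))
  truth_pos <- unique(as.character(truth_pos))
  all_electrodes <- unique(as.character(all_electrodes))
  if (!all(test_pos %in% all_electrodes) || !all(truth_pos %in% all_electrodes))
    stop_invalid("test and truth sets must be subsets of all_electrodes",
                 "ecogmap_invalid_input")
  a <- length(intersect(test_pos, truth_pos))
  b <- length(setdiff(test_pos, truth_pos))
  c_ <- length(setdiff(truth_pos, test_pos))
  d <- length(all_electrodes) - a - b - c_
  structure(list(A = a, B = b, C = c_, D = d), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> A=%d B=%d C=%d D=%d (n=%d)\n",
              x$A, x$B, x$C, x$D, x$A + x$B + x$C + x$D))
  invisible(x)
}

#' Sensitivity and specificity in percent
#'
#' `sensitivity = 100 * A / (A + C)`; `specificity = 100 * D / (B + D)`.
#'
#' @param cc a [confusion_counts()] object.
#' @return named numeric vector `c(sensitivity, specificity)` in percent.
#' @export
sensitivity_specificity <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  if (cc$A + cc$C == 0 || cc$B + cc$D == 0)
    stop_invalid("sensitivity/specificity undefined: empty margin",
                 "ecogmap_undefined_metric")
  c(sensitivity = 100 * cc$A / (cc$A + cc$C),
    specificity = 100 * cc$D / (cc$B + cc$D))
}

#' Chi-square independence test on a 2 x 2 confusion table
#'
#' Yates-continuity-corrected by default:
#' `chi2 = N * (|AD - BC| - N/2)^2 / ((A+B)(C+D)(A+C)(B+D))`.
#' The critical value at `alpha = 0.001`, df = 1 is 10.83.
#'
#' @param cc a [confusion_counts()] object.
#' @param yates apply the continuity correction (default `TRUE`).
#' @return list with `chi2`, `df = 1`, `p`.
#' @export
chi_square_independence <- function(cc, yates = TRUE) {
  stopifnot(inherits(cc, "confusion_counts"))
  a <- cc$A; b <- cc$B; c_ <- cc$C; d <- cc$D
  n <- a + b + c_ + d
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0))
    stop_invalid("chi-square undefined: zero marginal", "ecogmap_invalid_input")
  delta <- abs(a * d - b * c_)
  if (yates) delta <- max(0, delta - n / 2)
  chi2 <- n * delta^2 / prod(margins)
  list(chi2 = chi2, df = 1L, p = pchisq(chi2, 1, lower.tail = FALSE))
}

#' Topographic activation raster from per-electrode weights
#'
#' Sum of truncated spherical Gaussian kernels, one per electrode, each
#' multiplied by the electrode's weight (signed R2 or spectral
#' activation weight; non-significant electrodes get weight 0). The
#' kernel has a 25 mm support diameter; sigma is expressed relative to
#' the kernel radius (0.4 x 12.5 mm = 5 mm physical by default).
#'
#' @param grid an [electrode_grid()].
#' @param weights named numeric vector (names = channel labels); missing
#'   channels count as 0.
#' @param resolution_mm raster pixel size (default 0.5 mm).
#' @param kernel_diameter_mm support diameter (default 25).
#' @param sigma_rel sigma in units of the kernel radius (default 0.4).
#' @return list of class `activation_raster`: `x_mm`, `y_mm`, `values`
#'   (matrix, rows = y, cols = x) plus the kernel configuration.
#' @export
activation_map <- function(grid, weights, resolution_mm = 0.5,
                           kernel_diameter_mm = 25, sigma_rel = 0.4) {
  radius <- kernel_diameter_mm / 2
  sigma <- sigma_rel * radius
  w <- setNames(rep(0, nrow(grid)), grid$channel)
  if (!is.null(names(weights))) {
    known <- intersect(names(weights), grid$channel)
    w[known] <- weights[known]
  } else {
    if (length(weights) != nrow(grid))
      stop_invalid("unnamed weights must match the grid length",
                   "ecogmap_invalid_input")
    w[] <- weights
  }
  xs <- seq(min(grid$x_mm) - radius, max(grid$x_mm) + radius,
            by = resolution_mm)
  ys <- seq(min(grid$y_mm) - radius, max(grid$y_mm) + radius,
            by = resolution_mm)
  vals <- matrix(0, nrow = length(ys), ncol = length(xs))
  for (i in seq_len(nrow(grid))) {
    if (w[i] == 0) next
    dx2 <- (xs - grid$x_mm[i])^2
    dy2 <- (ys - grid$y_mm[i])^2
    d2 <- outer(dy2, dx2, `+`)
    k <- exp(-d2 / (2 * sigma^2))
    k[d2 > radius^2] <- 0
    vals <- vals + w[i] * k
  }
  structure(list(x_mm = xs, y_mm = ys, values = vals,
                 resolution_mm = resolution_mm,
                 kernel_diameter_mm = kernel_diameter_mm,
                 sigma_mm = sigma),
            class = "activation_raster")
}

#' Write a raster as a plain-text matrix (and optionally a PNG)
#' @param raster an `activation_raster`.
#' @param path output path for the text matrix (tab-separated).
#' @param png optional PNG path rendered with [graphics::image()].
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path, png = NULL) {
  utils::write.table(raster$values, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(png)) {
    grDevices::png(png, width = 800, height = 600)
    on.exit(grDevices::dev.off())
    graphics::image(raster$x_mm, raster$y_mm, t(raster$values),
                    xlab = "x (mm)", ylab = "y (mm)", useRaster = TRUE,
                    col = grDevices::hcl.colors(64, "RdBu", rev = TRUE))
  }
  invisible(path)
}

#' Clinical risk partition of electrodes
#'
#' Electrodes positive under both the temporal and the spectral map are
#' functional-convinced; electrodes positive under exactly one are
#' functional-high-risk (candidates for confirmatory stimulation);
#' electrodes positive under neither are negative.
#'
#' @param etam_flags,efam_flags named logical vectors over the same
#'   electrode set.
#' @return list with character vectors `functional_convinced`,
#'   `functional_high_risk`, `negative`.
#' @export
site_risk_partition <- function(etam_flags, efam_flags) {
  if (is.null(names(etam_flags)) || is.null(names(efam_flags)) ||
      !setequal(names(etam_flags), names(efam_flags)))
    stop_invalid("flags must be named over the same electrode set",
                 "ecogmap_invalid_input")
  efam_flags <- efam_flags[names(etam_flags)]
  both <- etam_flags & efam_flags
  one <- xor(etam_flags, efam_flags)
  list(functional_convinced = names(etam_flags)[both],
       functional_high_risk = names(etam_flags)[one],
       negative = names(etam_flags)[!both & !one])
}
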