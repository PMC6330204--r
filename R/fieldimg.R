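#' Two-band (red / near-infrared) camera image
#'
#' @param red,nir numeric matrices of equal dimension: digital numbers before
#'   calibration, reflectances after.
#' @param calibrated logical; has the image been calibrated to reflectance?
#' @param units `"dn"` or `"reflectance"`.
#' @return an object of class `twoband_image`.
#' @export
twoband_image <- function(red, nir, calibrated = FALSE,
                          units = if (calibrated) "reflectance" else "dn") {
  if (!identical(dim(red), dim(nir)))
    stop_bad_param("red and nir bands must be congruent")
  structure(list(red = red, nir = nir, calibrated = isTRUE(calibrated),
                 units = units), class = "twoband_image")
}

#' @export
print.twoband_image <- function(x, ...) {
  cat(sprintf("<twoband_image> %d x %d px, %s%s\n", nrow(x$red), ncol(x$red),
              x$units, if (x$calibrated) " (calibrated)" else ""))
  invisible(x)
}

#' Calibration target of known reflectance
#'
#' @param reflectance named `c(red=, nir=)` known target reflectances.
#' @param dn named `c(red=, nir=)` observed mean digital numbers over the
#'   target patch; must be positive.
#' @return an object of class `calibration_target`.
#' @export
calibration_target <- function(reflectance, dn) {
  for (b in c("red", "nir")) {
    if (is.na(reflectance[[b]]) || is.na(dn[[b]]))
      stop_bad_param("target must supply red and nir values")
  }
  if (any(dn <= 0))
    stop("calibration error: non-positive target digital number", call. = FALSE)
  structure(list(reflectance = reflectance[c("red", "nir")],
                 dn = dn[c("red", "nir")]), class = "calibration_target")
}

#' Measure a calibration target from its image
#'
#' Averages the digital numbers of a target patch and pairs them with the
#' target's known reflectances.
#'
#' @param image uncalibrated [twoband_image] of the target.
#' @param reflectance known `c(red=, nir=)` reflectances of the target.
#' @param bounds optional patch rectangle `c(row1, col1, row2, col2)`;
#'   defaults to the whole image.
#' @return a [calibration_target()].
#' @export
measure_target <- function(image, reflectance, bounds = NULL) {
  stopifnot(inherits(image, "twoband_image"))
  sub <- if (is.null(bounds)) image else delineate_roi(image, bounds)
  calibration_target(reflectance,
                     dn = c(red = mean(sub$red, na.rm = TRUE),
                            nir = mean(sub$nir, na.rm = TRUE)))
}

#' Calibrate a two-band image against a ground target
#'
#' Single-target multiplicative calibration: per-band gain
#' `k = known_reflectance / observed_DN`, applied to every pixel.
#'
#' @param image uncalibrated [twoband_image].
#' @param target a [calibration_target()].
#' @return calibrated [twoband_image] in reflectance units.
#' @export
calibrate <- function(image, target) {
  stopifnot(inherits(image, "twoband_image"), inherits(target, "calibration_target"))
  if (image$calibrated) stop_bad_param("image is already calibrated")
  gains <- unlist(target$reflectance) / unlist(target$dn)
  twoband_image(red = image$red * gains[["red"]],
                nir = image$nir * gains[["nir"]], calibrated = TRUE)
}

#' Two-point affine calibration (dark + light targets)
#'
#' Solves per-band gain and offset from two targets of differing reflectance:
#' `reflectance = gain * DN + offset`.
#'
#' @param image uncalibrated [twoband_image].
#' @param dark,light [calibration_target()]s with distinct digital numbers in
#'   each band.
#' @return calibrated [twoband_image].
#' @export
calibrate_affine <- function(image, dark, light) {
  stopifnot(inherits(image, "twoband_image"))
  if (image$calibrated) stop_bad_param("image is already calibrated")
  bands <- lapply(c(red = "red", nir = "nir"), function(b) {
    d <- c(dark$dn[[b]], light$dn[[b]])
    r <- c(dark$reflectance[[b]], light$reflectance[[b]])
    if (abs(diff(d)) < .Machine$double.eps)
      stop("calibration error: targets have identical digital numbers", call. = FALSE)
    gain <- diff(r) / diff(d)
    offset <- r[1] - gain * d[1]
    image[[b]] * gain + offset
  })
  twoband_image(red = bands$red, nir = bands$nir, calibrated = TRUE)
}

#' Compute an NDVI image from a calibrated two-band image
#'
#' Per pixel `(NIR - RED) / (NIR + RED)`; pixels where the denominator is zero
#' are undefined (`NA`).
#'
#' @param image calibrated [twoband_image].
#' @param force compute even for an uncalibrated image (digital-number NDVI is
#'   biased by differing band gains; off by default).
#' @return numeric NDVI matrix.
#' @export
compute_ndvi <- function(image, force = FALSE) {
  stopifnot(inherits(image, "twoband_image"))
  if (!image$calibrated && !force)
    stop("image is not calibrated; calibrate first or set force = TRUE", call. = FALSE)
  denom <- image$nir + image$red
  out <- (image$nir - image$red) / denom
  out[denom == 0] <- NA_real_
  out
}

#' Thermal matrix of ground surface temperatures
#'
#' @param m numeric matrix of temperatures (degrees C). Values outside the
#'   plausible field range (-20, 70) trigger a warning, not an error.
#' @param source optional source file identifier.
#' @return an object of class `thermal_matrix`.
#' @export
thermal_matrix <- function(m, source = NULL) {
  if (!all(is.finite(m)))
    stop_bad_param("thermal matrix must be finite")
  if (any(m < -20 | m > 70))
    warning("thermal values outside the plausible range (-20, 70) degrees C")
  structure(m, source = source, class = c("thermal_matrix", "matrix"))
}

#' Read a thermal snapshot CSV as a matrix
#'
#' Thermal snapshots are headerless delimiter-separated grids of temperatures
#' in degrees C, row-major.
#'
#' @param path file path.
#' @param delimiter field delimiter (default comma).
#' @return a [thermal_matrix].
#' @export
read_thermal_csv <- function(path, delimiter = ",") {
  m <- as.matrix(utils::read.table(path, sep = delimiter, header = FALSE))
  dimnames(m) <- NULL
  thermal_matrix(m, source = path)
}

#' Delineate a rectangular region of interest
#'
#' Subsets an image or matrix to the rectangle `c(row1, col1, row2, col2)`
#' (inclusive). Thermal inputs must yield exactly the standard 150 x 150-cell
#' extent used for every thermal sample.
#'
#' @param x a matrix, [thermal_matrix] or [twoband_image].
#' @param bounds integer rectangle `c(row1, col1, row2, col2)`.
#' @return the subset, same class as the input.
#' @export
delineate_roi <- function(x, bounds) UseMethod("delineate_roi")

check_bounds <- function(x, bounds) {
  if (length(bounds) != 4L) stop_bad_param("bounds must be c(row1, col1, row2, col2)")
  if (bounds[1] < 1 || bounds[2] < 1 || bounds[3] > nrow(x) || bounds[4] > ncol(x) ||
      bounds[3] < bounds[1] || bounds[4] < bounds[2])
    stop_bad_param("bounds out of range for a ", nrow(x), " x ", ncol(x), " input")
  bounds
}

#' @export
delineate_roi.matrix <- function(x, bounds) {
  b <- check_bounds(x, bounds)
  x[b[1]:b[3], b[2]:b[4], drop = FALSE]
}

#' @export
delineate_roi.thermal_matrix <- function(x, bounds) {
  b <- check_bounds(x, bounds)
  if (b[3] - b[1] + 1 != 150 || b[4] - b[2] + 1 != 150)
    stop("thermal region of interest must be exactly 150 x 150 cells", call. = FALSE)
  out <- unclass(x)[b[1]:b[3], b[2]:b[4], drop = FALSE]
  structure(out, source = attr(x, "source"), class = class(x))
}

#' @export
delineate_roi.twoband_image <- function(x, bounds) {
  twoband_image(red = delineate_roi(unclass(x$red), bounds),
                nir = delineate_roi(unclass(x$nir), bounds),
                calibrated = x$calibrated, units = x$units)
}

#' Summary statistics of a region of interest
#'
#' Mean, median, minimum, maximum and sample standard deviation (n-1
#' denominator) over the finite values of the region; undefined pixels are
#' excluded from the statistics and the pixel count.
#'
#' @param values numeric matrix/vector ([thermal_matrix] and NDVI subsets
#'   included).
#' @return an object of class `roi_summary` with fields mean, median, min,
#'   max, sd, n_pixels.
#' @export
summarize_roi <- function(values) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("region of interest has no defined values", call. = FALSE)
  structure(list(mean = mean(v), median = stats::median(v), min = min(v),
                 max = max(v), sd = if (length(v) > 1) stats::sd(v) else 0,
                 n_pixels = length(v)),
            class = "roi_summary")
}

#' @export
print.roi_summary <- function(x, ...) {
  cat(sprintf("<roi_summary> n=%d mean=%.4g median=%.4g min=%.4g max=%.4g sd=%.4g\n",
              x$n_pixels, x$mean, x$median, x$min, x$max, x$sd))
  invisible(x)
}

#' Validate an NDVI sample against the sensibility rule
#'
#' A calibrated NDVI sample is excluded when its region-of-interest mean falls
#' outside [-1, 1] or more than `max_out_frac` of its pixels do — the
#' quantified form of discarding samples whose target calibration produced
#' non-sensible values.
#'
#' @param ndvi numeric matrix of region-of-interest NDVI values.
#' @param max_out_frac maximum tolerated fraction of out-of-range pixels
#'   (default 0.05).
#' @return list with `accept` (logical), `reason` (`NA` when accepted) and the
#'   [summarize_roi()] of the sample.
#' @export
validate_ndvi_sample <- function(ndvi, max_out_frac = 0.05) {
  s <- summarize_roi(ndvi)
  v <- as.numeric(ndvi)
  v <- v[is.finite(v)]
  out_frac <- mean(v < -1 | v > 1)
  if (s$mean < -1 || s$mean > 1)
    list(accept = FALSE, reason = sprintf("mean NDVI %.3f outside [-1, 1]", s$mean),
         summary = s)
  else if (out_frac > max_out_frac)
    list(accept = FALSE,
         reason = sprintf("%.1f%% of pixels outside [-1, 1] (max %.1f%%)",
                          100 * out_frac, 100 * max_out_frac),
         summary = s)
  else list(accept = TRUE, reason = NA_character_, summary = s)
}
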