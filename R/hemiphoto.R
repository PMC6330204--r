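#' Hemispherical canopy image
#'
#' Wraps a 3-channel pixel array together with the fisheye geometry needed to
#' map pixels to view directions: the optical centre, the footprint radius and
#' the lens projection law.
#'
#' @param data numeric array `[rows, cols, 3]` of channel intensities
#'   (any monotone intensity scale; 0-255 by convention).
#' @param center optical centre as `c(row, col)`; defaults to the array centre.
#' @param radius footprint radius in pixels (distance from the centre at which
#'   the zenith angle reaches `max_zenith`); defaults to the largest inscribed
#'   radius.
#' @param lens projection law: `"equidistant"` (radius proportional to zenith)
#'   or `"equisolid"` (radius proportional to sin(zenith/2)).
#' @param max_zenith zenith angle (degrees) at the footprint edge; 90 for a
#'   full hemisphere.
#' @return an object of class `hemis_image`.
#' @export
hemis_image <- function(data, center = NULL, radius = NULL,
                        lens = c("equidistant", "equisolid"), max_zenith = 90) {
  lens <- match.arg(lens)
  if (length(dim(data)) != 3L || dim(data)[3] < 3L)
    stop_bad_param("data must be a [rows, cols, 3] array")
  nr <- dim(data)[1]; nc <- dim(data)[2]
  center <- center %||% c((nr + 1) / 2, (nc + 1) / 2)
  radius <- radius %||% (min(nr, nc) / 2 - 0.5)
  if (radius <= 0) stop_bad_param("footprint radius must be positive")
  structure(list(data = data, center = center, radius = radius,
                 lens = lens, max_zenith = max_zenith),
            class = "hemis_image")
}

#' @export
print.hemis_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hemis_image> %d x %d px, %s lens, footprint radius %.1f px, max zenith %g deg\n",
              d[1], d[2], x$lens, x$radius, x$max_zenith))
  invisible(x)
}

# geometry: per-pixel zenith (degrees); NA outside the footprint
pixel_zenith <- function(geom) {
  nr <- if (is.null(dim(geom$data))) geom$nrow else dim(geom$data)[1]
  nc <- if (is.null(dim(geom$data))) geom$ncol else dim(geom$data)[2]
  r <- sqrt(outer((seq_len(nr) - geom$center[1])^2,
                  (seq_len(nc) - geom$center[2])^2, `+`))
  frac <- r / geom$radius
  theta <- switch(geom$lens,
    equidistant = frac * geom$max_zenith,
    equisolid   = 2 * asin(pmin(1, frac * sin(geom$max_zenith * pi / 360))) * 180 / pi)
  theta[frac > 1] <- NA_real_
  theta
}

# per-pixel azimuth in [0, 360)
pixel_azimuth <- function(geom) {
  nr <- dim(geom$data)[1]; nc <- dim(geom$data)[2]
  dy <- matrix(seq_len(nr) - geom$center[1], nr, nc)
  dx <- matrix(seq_len(nc) - geom$center[2], nr, nc, byrow = TRUE)
  (atan2(dx, -dy) * 180 / pi) %% 360
}

#' Extract the blue band from a hemispherical image
#'
#' The blue channel gives maximum leaf/sky contrast (leaf absorption is near
#' total and sky scattering strongest in the blue), so all downstream
#' thresholding operates on it. The fisheye geometry travels with the result.
#'
#' @param image a [hemis_image].
#' @param band channel index to extract (default 3, the blue channel of an RGB
#'   array; configurable for cameras with other channel orders).
#' @return a single-channel image of class `hemis_band`.
#' @export
extract_blue_band <- function(image, band = 3L) {
  stopifnot(inherits(image, "hemis_image"))
  if (length(dim(image$data)) != 3L)
    stop_bad_param("input must have 3 channels; got a single-channel image")
  structure(list(data = image$data[, , band], center = image$center,
                 radius = image$radius, lens = image$lens,
                 max_zenith = image$max_zenith),
            class = "hemis_band")
}

footprint_mask <- function(band) !is.na(pixel_zenith(band))

#' Ridler-Calvard (isodata) intensity threshold
#'
#' Finds the fixed point of the isodata iteration
#' \eqn{T_{k+1} = (\mu_{\le T_k} + \mu_{>T_k})/2}: the threshold halfway
#' between the mean of the pixels at or below it and the mean of those above
#' it. Iteration starts from the global mean and stops when the update falls
#' below `tol`.
#'
#' @param band a `hemis_band`, or a plain numeric matrix.
#' @param footprint optional logical matrix restricting the pixels considered;
#'   defaults to the fisheye footprint for a `hemis_band`, all pixels for a
#'   matrix.
#' @param tol convergence tolerance in intensity units.
#' @param max_iter iteration cap.
#' @return the threshold intensity (numeric scalar).
#' @export
ridler_calvard_threshold <- function(band, footprint = NULL, tol = 0.01,
                                     max_iter = 100L) {
  v <- if (inherits(band, "hemis_band")) band$data else band
  footprint <- footprint %||%
    (if (inherits(band, "hemis_band")) footprint_mask(band) else !is.na(v))
  x <- v[footprint & is.finite(v)]
  if (length(unique(x)) < 2L)
    stop("degenerate image: fewer than 2 distinct intensities, no threshold exists",
         call. = FALSE)
  t_cur <- mean(x)
  for (i in seq_len(max_iter)) {
    lo <- x[x <= t_cur]; hi <- x[x > t_cur]
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t_cur) < tol) return(t_new)
    t_cur <- t_new
  }
  t_cur
}

#' Classify a blue-band image into vegetation and sky
#'
#' Pixels above the threshold are sky, pixels at or below it vegetation;
#' pixels outside the fisheye footprint are marked outside.
#'
#' @param band a `hemis_band` (or numeric matrix with `footprint`).
#' @param threshold intensity cut, typically from
#'   [ridler_calvard_threshold()].
#' @param footprint optional logical matrix; see
#'   [ridler_calvard_threshold()].
#' @return a `canopy_mask`: integer matrix with 1 = vegetation, 0 = sky,
#'   `NA` = outside footprint; geometry and the threshold used are attached.
#' @export
binarize <- function(band, threshold, footprint = NULL) {
  v <- if (inherits(band, "hemis_band")) band$data else band
  footprint <- footprint %||%
    (if (inherits(band, "hemis_band")) footprint_mask(band) else !is.na(v))
  m <- matrix(NA_integer_, nrow(v), ncol(v))
  m[footprint] <- ifelse(v[footprint] > threshold, 0L, 1L)
  structure(m,
            geometry = if (inherits(band, "hemis_band"))
              band[c("center", "radius", "lens", "max_zenith")] else NULL,
            threshold_used = threshold,
            class = c("canopy_mask", "matrix"))
}

mask_geometry <- function(mask) {
  g <- attr(mask, "geometry")
  if (is.null(g)) stop_bad_param("mask carries no fisheye geometry")
  g$data <- unclass(mask)
  g
}

#' Zenith-ring gap-fraction profile
#'
#' Bins the in-footprint pixels of a binary canopy mask into concentric zenith
#' rings covering (0, `max_zenith`] degrees and, within each ring, into
#' azimuth cells. The ring gap fraction is the sky share of classified pixels;
#' per-cell gap fractions are kept for the clumping correction. Fully
#' vegetated rings or cells (gap fraction 0) are replaced by the saturation
#' guard `1/n_pixels` so the later log transform stays defined.
#'
#' @param mask a `canopy_mask` from [binarize()].
#' @param ring_width_deg zenith ring width in degrees (default 5).
#' @param n_azimuth_cells azimuth cells per ring (default 8).
#' @param max_zenith outer zenith limit in degrees; 60 restricts the field of
#'   view to avoid mixed pixels near the horizon.
#' @return a `gap_profile`: list with `rings` (zenith_lo, zenith_hi,
#'   theta_mid, n_pixels, n_sky, p_gap) and `cells` (ring, cell, n_pixels,
#'   n_sky, p_gap) data frames.
#' @export
gap_fraction_profile <- function(mask, ring_width_deg = 5, n_azimuth_cells = 8,
                                 max_zenith = 60) {
  stopifnot(inherits(mask, "canopy_mask"))
  geom <- mask_geometry(mask)
  theta <- pixel_zenith(geom)
  phi <- pixel_azimuth(geom)
  m <- unclass(mask)
  keep <- !is.na(m) & !is.na(theta) & theta > 0 & theta <= max_zenith
  breaks <- seq(0, max_zenith, by = ring_width_deg)
  ring_id <- findInterval(theta[keep], breaks, left.open = TRUE, all.inside = TRUE)
  cell_id <- pmin(floor(phi[keep] / (360 / n_azimuth_cells)) + 1L, n_azimuth_cells)
  sky <- m[keep] == 0L
  n_rings <- length(breaks) - 1L
  ring_n <- tabulate(ring_id, n_rings)
  if (any(ring_n == 0L))
    stop(sprintf("empty zenith ring(s): %s",
                 paste(which(ring_n == 0L), collapse = ", ")), call. = FALSE)
  ring_sky <- as.numeric(tapply(sky, factor(ring_id, levels = seq_len(n_rings)), sum))
  ring_sky[is.na(ring_sky)] <- 0
  p_gap <- ring_sky / ring_n
  sat <- p_gap == 0
  p_gap[sat] <- 1 / ring_n[sat]
  rings <- data.frame(
    zenith_lo = breaks[-length(breaks)], zenith_hi = breaks[-1],
    theta_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
    n_pixels = ring_n, n_sky = ring_sky, p_gap = p_gap)

  key <- interaction(factor(ring_id, levels = seq_len(n_rings)),
                     factor(cell_id, levels = seq_len(n_azimuth_cells)))
  cn <- as.numeric(tapply(rep(1L, length(sky)), key, sum))
  cs <- as.numeric(tapply(sky, key, sum))
  grid <- expand.grid(ring = seq_len(n_rings), cell = seq_len(n_azimuth_cells))
  cells <- data.frame(ring = grid$ring, cell = grid$cell,
                      n_pixels = ifelse(is.na(cn), 0, cn),
                      n_sky = ifelse(is.na(cs), 0, cs))
  cells <- cells[cells$n_pixels > 0, , drop = FALSE]
  cells$p_gap <- cells$n_sky / cells$n_pixels
  csat <- cells$p_gap == 0
  cells$p_gap[csat] <- 1 / cells$n_pixels[csat]
  structure(list(rings = rings, cells = cells,
                 ring_width_deg = ring_width_deg,
                 n_azimuth_cells = n_azimuth_cells,
                 max_zenith = max_zenith, n_images = 1L),
            class = "gap_profile")
}

#' @export
print.gap_profile <- function(x, ...) {
  cat(sprintf("<gap_profile> %d rings over (0, %g] deg, %d azimuth cells, %d image(s)\n",
              nrow(x$rings), x$max_zenith, x$n_azimuth_cells, x$n_images))
  print(x$rings, row.names = FALSE)
  invisible(x)
}

#' Fractional vegetation cover of a binary mask
#'
#' Canopy closure as the percentage of classified pixels (zenith at or below
#' `max_zenith`) that are vegetation.
#'
#' @param mask a `canopy_mask`.
#' @param max_zenith zenith cut-off in degrees (default 60, matching the
#'   field-of-view restriction; set 10 for a nadir-cone definition).
#' @return cover in percent (0-100).
#' @export
fcover <- function(mask, max_zenith = 60) {
  stopifnot(inherits(mask, "canopy_mask"))
  theta <- pixel_zenith(mask_geometry(mask))
  m <- unclass(mask)
  zone <- !is.na(m) & !is.na(theta) & theta <= max_zenith
  if (!any(zone)) stop("no classified pixels within the zenith zone", call. = FALSE)
  100 * sum(m[zone] == 1L) / sum(zone)
}

#' Invert a gap-fraction profile to canopy structure
#'
#' Effective plant area index under the homogeneous-canopy gap model
#' \eqn{P(\theta) = \exp(-G \cdot L / \cos\theta)} with a spherical leaf-angle
#' distribution (G = 0.5): the ring statistic \eqn{-\ln \bar P(\theta)\cos\theta}
#' equals \eqn{G L} for every ring, so its pixel-count-weighted mean divided by
#' G gives the effective LAI using all rings. The Lang-Xiang clumping index
#' compares the log of the ring-mean gap fraction with the mean over azimuth
#' cells of the log cell gap fractions (log-averaging); true LAI is effective
#' LAI divided by the combined clumping index.
#'
#' @param profile a [gap_fraction_profile()] result (single image or pooled).
#' @param g projection coefficient (G-function); 0.5 for the spherical
#'   leaf-angle distribution.
#' @return a `canopy_structure`: fcover (%), lai_effective, clumping_index,
#'   lai, n_images.
#' @export
invert_lai <- function(profile, g = 0.5) {
  stopifnot(inherits(profile, "gap_profile"))
  r <- profile$rings
  if (any(r$n_pixels == 0)) stop("ring with zero pixels", call. = FALSE)
  w <- r$n_pixels
  k_hat <- sum(w * (-log(r$p_gap) * cos(r$theta_mid * pi / 180))) / sum(w)
  lai_eff <- k_hat / g

  # Lang-Xiang per ring: ln(ring mean P) / mean over cells of ln(cell P)
  omega_ring <- vapply(seq_len(nrow(r)), function(i) {
    cl <- profile$cells[profile$cells$ring == i, , drop = FALSE]
    num <- log(r$p_gap[i])
    den <- mean(log(cl$p_gap))
    if (den == 0) 1 else num / den
  }, numeric(1))
  omega <- sum(w * omega_ring) / sum(w)
  if (!is.finite(omega) || omega <= 0 || omega > 1) {
    if (is.finite(omega) && omega > 1 + 1e-9)
      warning("clumping index outside (0, 1]; clipped to 1")
    omega <- 1
  }
  fc <- 100 * (1 - sum(r$n_sky) / sum(r$n_pixels))
  structure(list(fcover = fc, lai_effective = lai_eff,
                 clumping_index = omega, lai = lai_eff / omega,
                 n_images = profile$n_images),
            class = "canopy_structure")
}

#' @export
print.canopy_structure <- function(x, ...) {
  cat(sprintf(
    "<canopy_structure> LAI %.3f (effective %.3f, clumping index %.3f), FCover %.1f%%, %d image(s)\n",
    x$lai, x$lai_effective, x$clumping_index, x$fcover, x$n_images))
  invisible(x)
}

#' Hinge-angle LAI estimate (cross-check)
#'
#' Single-ring estimator using the ring containing the 57.5 degree hinge
#' angle, where the G-function is nearly leaf-angle independent:
#' \eqn{L \approx -\ln \bar P(57.5^\circ)\cos(57.5^\circ)/0.5}.
#'
#' @param profile a `gap_profile` whose rings cover 57.5 degrees.
#' @return effective LAI (numeric scalar).
#' @export
lai_hinge <- function(profile) {
  stopifnot(inherits(profile, "gap_profile"))
  r <- profile$rings
  i <- which(r$zenith_lo < 57.5 & r$zenith_hi >= 57.5)
  if (length(i) != 1L) stop("no ring containing the 57.5 degree hinge angle", call. = FALSE)
  -log(r$p_gap[i]) * cos(r$theta_mid[i] * pi / 180) / 0.5
}

#' Pool gap-fraction profiles across images
#'
#' Sums ring-wise and cell-wise sky/total pixel counts across the profiles of
#' all images of a plot, then recomputes gap fractions (with the saturation
#' guard). Averaging gap fractions before the log transform is what makes the
#' plot-level estimate a single pooled inversion rather than a mean of
#' per-image LAIs.
#'
#' @param profiles list of `gap_profile`s sharing one ring scheme.
#' @return a pooled `gap_profile`.
#' @export
pool_profiles <- function(profiles) {
  if (length(profiles) == 0L) stop("empty profile list", call. = FALSE)
  stopifnot(all(vapply(profiles, inherits, logical(1), "gap_profile")))
  ref <- profiles[[1]]
  same <- vapply(profiles, function(p) {
    identical(p$rings[c("zenith_lo", "zenith_hi")], ref$rings[c("zenith_lo", "zenith_hi")]) &&
      p$n_azimuth_cells == ref$n_azimuth_cells
  }, logical(1))
  if (!all(same)) stop("profiles use differing ring schemes", call. = FALSE)
  rings <- ref$rings
  rings$n_pixels <- Reduce(`+`, lapply(profiles, function(p) p$rings$n_pixels))
  rings$n_sky <- Reduce(`+`, lapply(profiles, function(p) p$rings$n_sky))
  rings$p_gap <- rings$n_sky / rings$n_pixels
  sat <- rings$p_gap == 0
  rings$p_gap[sat] <- 1 / rings$n_pixels[sat]
  allc <- do.call(rbind, lapply(profiles, function(p) p$cells[c("ring", "cell", "n_pixels", "n_sky")]))
  agg <- stats::aggregate(cbind(n_pixels, n_sky) ~ ring + cell, data = allc, FUN = sum)
  agg <- agg[order(agg$ring, agg$cell), , drop = FALSE]
  agg$p_gap <- agg$n_sky / agg$n_pixels
  csat <- agg$p_gap == 0
  agg$p_gap[csat] <- 1 / agg$n_pixels[csat]
  structure(list(rings = rings, cells = agg,
                 ring_width_deg = ref$ring_width_deg,
                 n_azimuth_cells = ref$n_azimuth_cells,
                 max_zenith = ref$max_zenith,
                 n_images = sum(vapply(profiles, function(p) p$n_images, integer(1)))),
            class = "gap_profile")
}

#' Plot-level canopy structure from a set of hemispherical images
#'
#' Runs the full per-image chain (blue band, isodata threshold, binary mask,
#' ring profile) on every image of a plot, pools the ring-wise pixel counts
#' across images and inverts once. FCover is reported per image and as the
#' plot mean.
#'
#' @param images list of [hemis_image] objects.
#' @param ring_width_deg,n_azimuth_cells,max_zenith see
#'   [gap_fraction_profile()].
#' @param g projection coefficient, see [invert_lai()].
#' @param band blue-band index, see [extract_blue_band()].
#' @return a `canopy_structure` with an extra `fcover_per_image` field.
#' @export
plot_lai <- function(images, ring_width_deg = 5, n_azimuth_cells = 8,
                     max_zenith = 60, g = 0.5, band = 3L) {
  if (length(images) == 0L) stop("empty image list", call. = FALSE)
  masks <- lapply(images, function(im) {
    b <- extract_blue_band(im, band = band)
    binarize(b, ridler_calvard_threshold(b))
  })
  profiles <- lapply(masks, gap_fraction_profile,
                     ring_width_deg = ring_width_deg,
                     n_azimuth_cells = n_azimuth_cells, max_zenith = max_zenith)
  out <- invert_lai(pool_profiles(profiles), g = g)
  fc <- vapply(masks, fcover, numeric(1), max_zenith = max_zenith)
  out$fcover_per_image <- fc
  out$fcover <- mean(fc)
  out
}
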