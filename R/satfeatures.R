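#' Pixel-QA filtering rule
#'
#' The QA codes of the Landsat surface-reflectance product that indicate clear
#' conditions, and the codes flagging water bodies. Only clear pixels are
#' retained by [apply_qa_mask()]; water and every other code (clouds, haze,
#' shadow, fill) are set undefined.
#'
#' @param clear_codes integer QA values accepted as clear land.
#' @param water_codes integer QA values flagging water (recorded for
#'   reporting; water is excluded like any non-clear code).
#' @return an object of class `qa_rule`.
#' @export
qa_rule <- function(clear_codes = c(322, 386, 834, 898, 1346),
                    water_codes = c(324, 388, 836, 900, 1348)) {
  if (length(intersect(clear_codes, water_codes)) > 0)
    stop_bad_param("clear and water code sets must be disjoint")
  structure(list(clear_codes = clear_codes, water_codes = water_codes),
            class = "qa_rule")
}

#' Mask a raster stack by its pixel-QA band
#'
#' Pixels whose QA code is in the clear list are retained; all other pixels
#' (water, cloud, haze, anything else) become undefined in every band.
#'
#' @param stack a [raster_stack] containing a `QA` band.
#' @param rule a [qa_rule()].
#' @return the masked stack.
#' @export
apply_qa_mask <- function(stack, rule = qa_rule()) {
  stopifnot(inherits(stack, "raster_stack"), inherits(rule, "qa_rule"))
  if (!"QA" %in% names(stack)) stop("stack has no QA band", call. = FALSE)
  keep <- matrix(stack$QA %in% rule$clear_codes, nrow(stack$QA), ncol(stack$QA))
  out <- lapply(unclass(stack), function(m) { m[!keep] <- NA_real_; m })
  do.call(raster_stack, c(out, list(transform = attr(stack, "transform"))))
}

#' Vegetation index rasters from red and near-infrared reflectance
#'
#' NDVI `(N-R)/(N+R)`, MSAVI2 `(2N+1-sqrt((2N+1)^2-8(N-R)))/2` and EVI2
#' `2.5(N-R)/(N+2.4R+1)`. Undefined inputs propagate; an NDVI denominator of
#' zero is undefined.
#'
#' @param red,nir congruent reflectance matrices in [0, 1].
#' @return list of matrices `ndvi`, `msavi2`, `evi2`.
#' @export
vegetation_indices <- function(red, nir) {
  if (!identical(dim(red), dim(nir)))
    stop_bad_param("red and nir must be congruent")
  denom <- nir + red
  ndvi <- (nir - red) / denom
  ndvi[!is.na(denom) & denom == 0] <- NA_real_
  msavi2 <- (2 * nir + 1 - sqrt((2 * nir + 1)^2 - 8 * (nir - red))) / 2
  evi2 <- 2.5 * (nir - red) / (nir + 2.4 * red + 1)
  list(ndvi = ndvi, msavi2 = msavi2, evi2 = evi2)
}

# shift a matrix by (dr, dc), padding with NA
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# global equal-width quantization to `levels` grey levels (0-based)
quantize_band <- function(band, levels) {
  rng <- range(band, finite = TRUE)
  if (!all(is.finite(rng)) || rng[1] == rng[2]) {
    warning("constant band: all pixels fall in one grey level")
    q <- band
    q[is.finite(band)] <- 0
    return(q)
  }
  q <- floor((band - rng[1]) / (rng[2] - rng[1]) * levels)
  pmin(q, levels - 1)
}

#' Grey-level co-occurrence textures (MEAN and DISSIMILARITY)
#'
#' The band is quantized to `levels` equal-width grey levels over its global
#' finite range. For each pixel, a symmetric co-occurrence matrix is
#' accumulated over the vertical neighbour pairs (the 90-degree offset: one
#' row up, same column) inside the `window` x `window` window centred there,
#' normalized to probabilities p(i, j). MEAN is the expected grey level
#' `sum i p(i,j)`; DISSIMILARITY is `sum |i-j| p(i,j)`. Windows touching the
#' image edge or containing undefined pixels are undefined.
#'
#' @param band numeric matrix.
#' @param levels grey levels (default 64).
#' @param window odd window size (default 3).
#' @return list of matrices `mean` and `dissimilarity`.
#' @export
glcm_textures <- function(band, levels = 64, window = 3) {
  if (levels < 2) stop_bad_param("levels must be >= 2")
  if (window %% 2 != 1) stop_bad_param("window must be odd")
  q <- quantize_band(band, levels)
  half <- (window - 1) / 2
  # vertical pair positions relative to the centre: lower member at (dr, dc)
  # with its upper neighbour at (dr - 1, dc); both must lie inside the window
  sum_lvl <- matrix(0, nrow(q), ncol(q))
  sum_dis <- matrix(0, nrow(q), ncol(q))
  npairs <- 0L
  for (dc in -half:half) for (dr in (-half + 1):half) {
    a <- shift_mat(q, -dr, -dc)        # level at window cell (dr, dc)
    b <- shift_mat(q, -(dr - 1), -dc)  # its upper neighbour
    sum_lvl <- sum_lvl + a + b         # symmetric: both orderings counted
    sum_dis <- sum_dis + 2 * abs(a - b)
    npairs <- npairs + 1L
  }
  n_entries <- 2 * npairs
  out_mean <- sum_lvl / n_entries
  out_dis <- sum_dis / n_entries
  # any window cell undefined -> undefined output (includes edges)
  cover <- matrix(0, nrow(q), ncol(q))
  for (dc in -half:half) for (dr in -half:half)
    cover <- cover + shift_mat(q, -dr, -dc)
  bad <- !is.finite(cover)
  out_mean[bad] <- NA_real_
  out_dis[bad] <- NA_real_
  list(mean = out_mean, dissimilarity = out_dis)
}

#' Focal (moving-window) mean and standard deviation
#'
#' Sliding-window statistics centred on each pixel. Undefined values are
#' excluded from the window sample and windows are truncated at the image
#' edge; the standard deviation is the sample standard deviation and is
#' undefined for windows with fewer than 2 defined values.
#'
#' @param raster numeric matrix.
#' @param window odd window size in pixels (>= 3; default 9, the nearest odd
#'   window to a nominal 8-pixel moving window).
#' @return list of matrices `mean` and `sd`.
#' @export
focal_stats <- function(raster, window = 9) {
  if (window < 3) stop_bad_param("window must be >= 3")
  if (window %% 2 != 1) stop_bad_param("window must be odd")
  half <- (window - 1) / 2
  s <- matrix(0, nrow(raster), ncol(raster))
  s2 <- matrix(0, nrow(raster), ncol(raster))
  n <- matrix(0, nrow(raster), ncol(raster))
  for (dc in -half:half) for (dr in -half:half) {
    v <- shift_mat(raster, -dr, -dc)
    ok <- is.finite(v)
    s[ok] <- s[ok] + v[ok]
    s2[ok] <- s2[ok] + v[ok]^2
    n <- n + ok
  }
  mu <- ifelse(n >= 1, s / n, NA_real_)
  varr <- ifelse(n >= 2, pmax(0, (s2 - s^2 / n)) / (n - 1), NA_real_)
  list(mean = mu, sd = sqrt(varr))
}

#' Derive the full satellite predictor stack
#'
#' Applies the QA mask, then computes the vegetation indices (NDVI, MSAVI2,
#' EVI2), the grey-level co-occurrence MEAN and DISSIMILARITY textures of the
#' RED, NIR and SWIR1 bands, and the focal mean/sd of NDVI, returning one
#' stack holding every candidate predictor layer. Layer names follow the
#' field convention: REDM/REDD, NIRM/NIRD, SWIRM/SWIRD for textures,
#' NDVIMFocal/NDVISD for the focal NDVI statistics.
#'
#' @param stack a [raster_stack] with RED, NIR, SWIR1 and QA bands.
#' @param rule a [qa_rule()].
#' @param levels,texture_window see [glcm_textures()].
#' @param focal_window see [focal_stats()].
#' @return a [raster_stack] with the original bands plus the derived layers.
#' @export
derive_feature_stack <- function(stack, rule = qa_rule(), levels = 64,
                                 texture_window = 3, focal_window = 9) {
  stopifnot(inherits(stack, "raster_stack"))
  masked <- apply_qa_mask(stack, rule)
  vi <- vegetation_indices(masked$RED, masked$NIR)
  tex <- lapply(list(RED = masked$RED, NIR = masked$NIR, SWIR = masked$SWIR1),
                glcm_textures, levels = levels, window = texture_window)
  foc <- focal_stats(vi$ndvi, window = focal_window)
  stack_set(masked,
            NDVI = vi$ndvi, MSAVI2 = vi$msavi2, EVI2 = vi$evi2,
            REDM = tex$RED$mean, REDD = tex$RED$dissimilarity,
            NIRM = tex$NIR$mean, NIRD = tex$NIR$dissimilarity,
            SWIRM = tex$SWIR$mean, SWIRD = tex$SWIR$dissimilarity,
            NDVIMFocal = foc$mean, NDVISD = foc$sd)
}

#' Sample stack layers at plot locations into a feature table
#'
#' @param stack a [raster_stack] (typically from [derive_feature_stack()]).
#' @param rows,cols integer pixel indices of the plots.
#' @param responses optional data frame of plot-level responses (e.g. columns
#'   `lai`, `fcover`) bound to the sampled features row-wise.
#' @return data frame: one row per plot, one column per layer (plus
#'   responses).
#' @export
extract_features <- function(stack, rows, cols, responses = NULL) {
  stopifnot(inherits(stack, "raster_stack"), length(rows) == length(cols))
  out <- as.data.frame(lapply(unclass(stack), function(m)
    m[cbind(rows, cols)]))
  if (!is.null(responses)) out <- cbind(out, responses)
  out
}
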