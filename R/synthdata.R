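#' Parameters for a synthetic hemispherical canopy scene
#'
#' Describes a homogeneous (or optionally clumped) canopy of known plant area
#' index viewed through a fisheye lens. The generative model is the standard
#' gap model: a ray at zenith angle \eqn{\theta} passes unobstructed with
#' probability \eqn{P(\theta) = \exp(-G \cdot L / \cos\theta)}.
#'
#' @param true_lai plant area index of the simulated stand (m^2/m^2, >= 0).
#' @param projection_coefficient G-function value; 0.5 = spherical leaf-angle
#'   distribution.
#' @param image_size image side length in pixels (>= 64).
#' @param lens projection law, `"equidistant"` or `"equisolid"`.
#' @param clumped if `TRUE`, azimuth sectors get gamma-distributed density
#'   multipliers (mean 1), producing non-random foliage dispersion and a
#'   clumping index below 1; the sector-mean density still equals `true_lai`.
#' @param clump_shape gamma shape of the sector multipliers (smaller = more
#'   clumped).
#' @param n_sectors number of azimuth sectors used in clumped mode.
#' @param seed integer seed fixing all randomness.
#' @return a `canopy_scene_params` list.
#' @export
canopy_scene_params <- function(true_lai, projection_coefficient = 0.5,
                                image_size = 512, lens = "equidistant",
                                clumped = FALSE, clump_shape = 2,
                                n_sectors = 8, seed = 1) {
  check_scalar(true_lai, "true_lai", lower = 0)
  check_scalar(projection_coefficient, "projection_coefficient", lower = 0)
  check_scalar(image_size, "image_size", lower = 64)
  structure(list(true_lai = true_lai,
                 projection_coefficient = projection_coefficient,
                 image_size = as.integer(image_size), lens = lens,
                 clumped = isTRUE(clumped), clump_shape = clump_shape,
                 n_sectors = as.integer(n_sectors), seed = as.integer(seed)),
            class = "canopy_scene_params")
}

#' Generate a synthetic hemispherical photograph
#'
#' Classifies each in-footprint pixel as sky or vegetation by an independent
#' Bernoulli draw with gap probability \eqn{\exp(-G L / \cos\theta)} at the
#' pixel's zenith angle, then renders sky pixels bright and vegetation pixels
#' dark (maximum contrast in the blue channel) with mild Gaussian sensor
#' noise. Deterministic under a fixed seed.
#'
#' @param params a [canopy_scene_params()].
#' @return a [hemis_image] whose `"truth"` attribute records the generating
#'   parameters and the true per-pixel gap probabilities.
#' @export
gen_hemiphoto <- function(params) {
  stopifnot(inherits(params, "canopy_scene_params"))
  n <- params$image_size
  geom <- list(data = array(0, c(n, n, 3)), center = c((n + 1) / 2, (n + 1) / 2),
               radius = n / 2 - 0.5, lens = params$lens, max_zenith = 90)
  theta <- pixel_zenith(geom)
  inside <- !is.na(theta)
  g <- params$projection_coefficient
  lai_px <- matrix(params$true_lai, n, n)
  with_seed(params$seed, {
    if (params$clumped) {
      phi <- pixel_azimuth(geom)
      sector <- pmin(floor(phi / (360 / params$n_sectors)) + 1L, params$n_sectors)
      mult <- stats::rgamma(params$n_sectors, shape = params$clump_shape,
                            rate = params$clump_shape)
      mult <- mult / mean(mult)   # sector-mean density exactly true_lai
      lai_px[] <- params$true_lai * mult[sector]
    }
    p_gap <- exp(-g * lai_px / cos(pmin(theta, 89.9) * pi / 180))
    sky <- matrix(FALSE, n, n)
    sky[inside] <- stats::runif(sum(inside)) < p_gap[inside]
    img <- array(0, c(n, n, 3))
    base <- list(sky = c(180, 200, 235), veg = c(45, 60, 20))
    for (ch in 1:3) {
      plane <- matrix(0, n, n)
      plane[inside] <- ifelse(sky[inside], base$sky[ch], base$veg[ch]) +
        stats::rnorm(sum(inside), sd = 8)
      img[, , ch] <- pmin(pmax(plane, 0), 255)
    }
  })
  out <- hemis_image(img, center = geom$center, radius = geom$radius,
                     lens = params$lens, max_zenith = 90)
  attr(out, "truth") <- list(params = params, p_gap = p_gap, sky = sky)
  out
}

#' Generate a synthetic ground scene (two-band, target, thermal)
#'
#' Builds the three inputs of one NDVI/thermal sample point: an uncalibrated
#' two-band camera image whose digital numbers encode band reflectances of
#' known NDVI through fixed per-band gains, a calibration-target image of
#' known reflectance under the same gains, and a thermal matrix with the
#' stated mean and spread.
#'
#' @param ndvi_true true scene NDVI in [-1, 1].
#' @param temp_mean,temp_sd mean and standard deviation (degrees C) of the
#'   thermal matrix; `temp_sd = 0` gives a constant matrix.
#' @param size image/matrix side length in pixels (>= 150 so a 150 x 150
#'   thermal region of interest fits).
#' @param seed integer seed.
#' @param dn_noise_sd optional Gaussian digital-number noise on the two-band
#'   image (default 0: homogeneous patch).
#' @return list with `twoband` ([twoband_image], uncalibrated), `target`
#'   (uncalibrated [twoband_image] of the reflectance target),
#'   `target_reflectance` (named red/nir reflectances), `thermal`
#'   ([thermal_matrix]) and `truth`.
#' @export
gen_ground_scene <- function(ndvi_true, temp_mean = 25, temp_sd = 1,
                             size = 200, seed = 1, dn_noise_sd = 0) {
  check_scalar(ndvi_true, "ndvi_true", lower = -1, upper = 1)
  check_scalar(temp_sd, "temp_sd", lower = 0)
  check_scalar(size, "size", lower = 150)
  size <- as.integer(size)
  gains <- c(red = 0.0025, nir = 0.0020)        # reflectance per digital number
  refl <- c(red = 0.25 * (1 - ndvi_true), nir = 0.25 * (1 + ndvi_true))
  target_refl <- c(red = 0.35, nir = 0.35)
  with_seed(seed, {
    mk <- function(base_dn) {
      m <- matrix(base_dn, size, size)
      if (dn_noise_sd > 0) m <- m + stats::rnorm(size^2, sd = dn_noise_sd)
      pmax(m, 0)
    }
    tb <- twoband_image(red = mk(refl[["red"]] / gains[["red"]]),
                        nir = mk(refl[["nir"]] / gains[["nir"]]))
    tg <- twoband_image(red = mk(target_refl[["red"]] / gains[["red"]]),
                        nir = mk(target_refl[["nir"]] / gains[["nir"]]))
    th <- matrix(stats::rnorm(size^2, mean = temp_mean, sd = temp_sd), size, size)
  })
  list(twoband = tb, target = tg, target_reflectance = target_refl,
       thermal = thermal_matrix(th),
       truth = list(ndvi_true = ndvi_true, temp_mean = temp_mean,
                    temp_sd = temp_sd, gains = gains, seed = seed))
}

#' Parameters for a synthetic plot-level dataset
#'
#' Encodes the transect/plot sampling design and the linear (or
#' air-temperature interaction) relationships used as simulation truth.
#' Defaults follow the habitat composition of a 34-plot field campaign and
#' plot-scale regression coefficients typical of below-canopy microclimate:
#' ground temperature declining about 1.2 degrees C per LAI unit from an
#' intercept near 27.4, and ground NDVI declining 0.09 per LAI unit from 0.57.
#'
#' @param n_plots number of plots (>= 4).
#' @param habitat_mix named proportions over grassland, bush, edge, forest,
#'   woodland, plantation; must sum to 1.
#' @param coef_thermal `c(intercept, slope)` for thermal_ground ~ LAI.
#' @param coef_ndvi `c(intercept, slope)` for ndvi_down ~ LAI.
#' @param coef_interaction optional length-4 vector
#'   `c(b0, b_struct, b_T, b_interact)` for
#'   thermal_ground ~ FCover * T_air; when supplied it replaces the linear
#'   thermal truth.
#' @param noise_sd named residual standard deviations `c(thermal=, ndvi=)`
#'   (>= 0).
#' @param t_air_range air-temperature interval (degrees C) sampled uniformly.
#' @param seed integer seed.
#' @return a `plot_sim_params` list.
#' @export
plot_sim_params <- function(n_plots = 34,
                            habitat_mix = c(grassland = 6, bush = 1, edge = 11,
                                            forest = 11, woodland = 1,
                                            plantation = 4) / 34,
                            coef_thermal = c(27.4, -1.19),
                            coef_ndvi = c(0.57, -0.09),
                            coef_interaction = NULL,
                            noise_sd = c(thermal = 2.0, ndvi = 0.15),
                            t_air_range = c(21, 29), seed = 1) {
  if (n_plots < 4) stop_bad_param("n_plots must be >= 4 for model fitting")
  habs <- c("grassland", "bush", "edge", "forest", "woodland", "plantation")
  if (!all(names(habitat_mix) %in% habs))
    stop_bad_param("habitat_mix names must be among: ", paste(habs, collapse = ", "))
  if (abs(sum(habitat_mix) - 1) > 1e-8)
    stop_bad_param("habitat_mix proportions must sum to 1")
  if (any(noise_sd < 0)) stop_bad_param("noise_sd must be >= 0")
  if (!is.null(coef_interaction) && length(coef_interaction) != 4L)
    stop_bad_param("coef_interaction must have 4 elements (b0, b_struct, b_T, b_interact)")
  structure(list(n_plots = as.integer(n_plots), habitat_mix = habitat_mix,
                 coef_thermal = coef_thermal, coef_ndvi = coef_ndvi,
                 coef_interaction = coef_interaction, noise_sd = noise_sd,
                 t_air_range = t_air_range, seed = as.integer(seed)),
            class = "plot_sim_params")
}

# largest-remainder allocation of n plots to habitat proportions
allocate_habitats <- function(n, mix) {
  base <- floor(mix * n)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(mix * n - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(names(mix), times = base)
}

#' Generate a synthetic plot-level dataset
#'
#' Emulates a transect/plot field table: habitats allocated by the stated
#' proportions, per-habitat LAI ranges, fractional cover tied to LAI through a
#' light-extinction curve, and responses generated from the stated linear or
#' interaction truth plus Gaussian noise. Grassland plots carry no tree
#' measurements (`NA` canopy fields) so the treeless-defaults rule can be
#' exercised downstream; their responses are generated at LAI = 0, FCover = 0.
#'
#' @param params a [plot_sim_params()].
#' @return data frame with plot_id, transect_id, habitat, lai, fcover,
#'   ndvi_up, ndvi_down, thermal_ground, t_air; the generating truth is
#'   attached as attribute `"truth"`.
#' @export
gen_plot_dataset <- function(params) {
  stopifnot(inherits(params, "plot_sim_params"))
  n <- params$n_plots
  lai_range <- list(grassland = c(0, 0), bush = c(0.2, 1), edge = c(0.5, 3),
                    forest = c(2, 6), woodland = c(1, 3), plantation = c(1.5, 5))
  with_seed(params$seed, {
    habitat <- sample(allocate_habitats(n, params$habitat_mix))
    lai <- vapply(habitat, function(h)
      stats::runif(1, lai_range[[h]][1], lai_range[[h]][2]), numeric(1))
    fc <- 100 * (1 - exp(-0.65 * lai))
    t_air <- stats::runif(n, params$t_air_range[1], params$t_air_range[2])
    ndvi_up <- ifelse(habitat == "grassland", -1,
                      pmin(0.9, 0.2 + 0.12 * lai) + stats::rnorm(n, sd = 0.03))
    if (is.null(params$coef_interaction)) {
      b <- params$coef_thermal
      thermal <- b[1] + b[2] * lai + stats::rnorm(n, sd = params$noise_sd[["thermal"]])
    } else {
      b <- params$coef_interaction
      thermal <- b[1] + b[2] * fc + b[3] * t_air + b[4] * fc * t_air +
        stats::rnorm(n, sd = params$noise_sd[["thermal"]])
    }
    a <- params$coef_ndvi
    ndvi_down <- a[1] + a[2] * lai + stats::rnorm(n, sd = params$noise_sd[["ndvi"]])
  })
  grass <- habitat == "grassland"
  out <- data.frame(
    plot_id = sprintf("P%02d", seq_len(n)),
    transect_id = sprintf("T%02d", (seq_len(n) - 1) %/% 3 + 1),
    habitat = habitat,
    lai = ifelse(grass, NA_real_, lai),
    fcover = ifelse(grass, NA_real_, fc),
    ndvi_up = ifelse(grass, NA_real_, ndvi_up),
    ndvi_down = ndvi_down, thermal_ground = thermal, t_air = t_air,
    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(params = params, lai = lai, fcover = fc)
  out
}

#' Parameters for a synthetic Landsat-like scene
#'
#' A smooth random true-LAI field drives RED/NIR/SWIR1 surface reflectances
#' through a monotone forward model (NIR increasing, RED/SWIR1 decreasing with
#' LAI) plus Gaussian noise; a pixel-QA band scatters clear, water and other
#' codes at stated proportions.
#'
#' @param grid_size scene side length in pixels.
#' @param lai_range range of the true LAI field.
#' @param smoothness Gaussian blur standard deviation (pixels) of the LAI
#'   field; larger = smoother landscape.
#' @param noise_sd reflectance noise standard deviation.
#' @param qa_props named proportions `c(clear=, water=, other=)`.
#' @param seed integer seed.
#' @return a `landsat_sim_params` list.
#' @export
landsat_sim_params <- function(grid_size = 100, lai_range = c(0, 6),
                               smoothness = 7, noise_sd = 0.01,
                               qa_props = c(clear = 0.8, water = 0.1, other = 0.1),
                               seed = 1) {
  check_scalar(grid_size, "grid_size", lower = 16)
  if (abs(sum(qa_props) - 1) > 1e-8) stop_bad_param("qa_props must sum to 1")
  check_scalar(noise_sd, "noise_sd", lower = 0)
  structure(list(grid_size = as.integer(grid_size), lai_range = lai_range,
                 smoothness = smoothness, noise_sd = noise_sd,
                 qa_props = qa_props, seed = as.integer(seed)),
            class = "landsat_sim_params")
}

# smooth standard-normal-ish field by separable Gaussian convolution
smooth_field <- function(n, sigma) {
  z <- matrix(stats::rnorm(n * n), n, n)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  pad <- function(m) m[c(rep(1, half), seq_len(nrow(m)), rep(nrow(m), half)), , drop = FALSE]
  conv_rows <- function(m) {
    mp <- pad(m)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + nrow(m) - 1), , drop = FALSE]
    out
  }
  t(conv_rows(t(conv_rows(z))))
}

# monotone forward model: reflectance as a function of LAI
landsat_forward <- function(lai) {
  list(RED = 0.03 + 0.25 * exp(-0.50 * lai),
       NIR = 0.12 + 0.38 * (1 - exp(-0.35 * lai)),
       SWIR1 = 0.06 + 0.28 * exp(-0.30 * lai))
}

qa_code_lists <- function() {
  list(clear = c(322, 386, 834, 898, 1346),
       water = c(324, 388, 836, 900, 1348),
       other = c(328, 392, 480, 992))
}

#' Generate a synthetic Landsat-like raster scene
#'
#' @param params a [landsat_sim_params()].
#' @return list with `stack` (a [raster_stack] of RED, NIR, SWIR1, QA),
#'   `true_lai` (matrix) and `truth` (parameters).
#' @export
gen_landsat_scene <- function(params) {
  stopifnot(inherits(params, "landsat_sim_params"))
  n <- params$grid_size
  with_seed(params$seed, {
    f <- smooth_field(n, params$smoothness)
    f <- (f - min(f)) / (max(f) - min(f))
    lai <- params$lai_range[1] + f * diff(params$lai_range)
    refl <- landsat_forward(lai)
    if (params$noise_sd > 0)
      refl <- lapply(refl, function(m) m + stats::rnorm(n * n, sd = params$noise_sd))
    refl <- lapply(refl, function(m) pmin(pmax(m, 0), 1))
    codes <- qa_code_lists()
    cls <- sample(names(params$qa_props), n * n, replace = TRUE,
                  prob = params$qa_props)
    qa <- matrix(0, n, n)
    for (cl in names(codes))
      if (any(cls == cl))
        qa[cls == cl] <- sample(codes[[cl]], sum(cls == cl), replace = TRUE)
  })
  stack <- raster_stack(RED = refl$RED, NIR = refl$NIR, SWIR1 = refl$SWIR1, QA = qa)
  list(stack = stack, true_lai = lai,
       truth = list(params = params, qa_class = matrix(cls, n, n)))
}
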