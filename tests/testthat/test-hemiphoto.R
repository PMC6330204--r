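test_that("blue-band extraction returns the configured channel unchanged", {
  arr <- array(0, c(64, 64, 3))
  arr[, , 1] <- 10; arr[, , 2] <- 20; arr[, , 3] <- 30
  img <- hemis_image(arr)
  expect_true(all(extract_blue_band(img)$data == 30))
  expect_true(all(extract_blue_band(img, band = 1)$data == 10))
  # geometry travels with the band
  b <- extract_blue_band(img)
  expect_equal(b$radius, img$radius)
  # sky pixels brighter than vegetation in the generator's blue channel
  g <- gen_hemiphoto(canopy_scene_params(2, image_size = 128, seed = 1))
  sky <- attr(g, "truth")$sky
  blue <- extract_blue_band(g)$data
  inside <- !is.na(understorey:::pixel_zenith(g))
  expect_gt(mean(blue[inside & sky]), mean(blue[inside & !sky]))
})

test_that("isodata threshold: fixed point, symmetric two-class case, errors", {
  m <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  expect_equal(ridler_calvard_threshold(m), 105)
  expect_error(ridler_calvard_threshold(matrix(7, 5, 5)), "degenerate")
})

test_that("isodata threshold equals the exhaustive 8-bit scan oracle", {
  set.seed(101)
  for (i in 1:100) {
    # bimodal-ish random 8-bit images
    n <- 400
    x <- c(round(rnorm(n / 2, mean = runif(1, 40, 100), sd = 20)),
           round(rnorm(n / 2, mean = runif(1, 140, 220), sd = 25)))
    x <- pmin(pmax(x, 0), 255)
    if (length(unique(x)) < 2) next
    m <- matrix(x, 20, 20)
    thr <- ridler_calvard_threshold(m, tol = 1e-9, max_iter = 1000)
    fixed <- isodata_scan_oracle(x)
    expect_true(any(abs(fixed - thr) < 1e-6),
                label = sprintf("iteration %d: threshold %.4f in scan set {%s}",
                                i, thr, paste(round(fixed, 4), collapse = ", ")))
  }
})

test_that("threshold and mask are equivariant under affine intensity maps", {
  set.seed(7)
  m <- matrix(sample(0:255, 900, replace = TRUE), 30, 30)
  t0 <- ridler_calvard_threshold(m, tol = 1e-9)
  for (ab in list(c(2, 10), c(0.5, -3))) {
    t1 <- ridler_calvard_threshold(ab[1] * m + ab[2], tol = 1e-9)
    expect_equal(t1, ab[1] * t0 + ab[2], tolerance = 1e-6)
    expect_equal(unclass(binarize(m, t0)), unclass(binarize(ab[1] * m + ab[2], t1)),
                 ignore_attr = TRUE)
  }
})

test_that("binarize maps intensities to sky/vegetation/outside", {
  b <- band_from_matrix(matrix(100, 32, 32))
  all_sky <- binarize(b, 50)
  inside <- !is.na(unclass(all_sky))
  expect_true(all(unclass(all_sky)[inside] == 0L))
  all_veg <- binarize(b, 100)   # threshold = max intensity -> all vegetation
  expect_true(all(unclass(all_veg)[inside] == 1L))
  # outside-footprint pixels are flagged outside
  expect_true(all(is.na(unclass(all_sky)[!inside])))
  expect_gt(sum(!inside), 0)
})

test_that("gap-fraction profile: trivial masks, saturation guard, empty rings", {
  b <- band_from_matrix(matrix(100, 128, 128))
  sky_prof <- gap_fraction_profile(binarize(b, 50))
  expect_true(all(sky_prof$rings$p_gap == 1))
  veg_prof <- gap_fraction_profile(binarize(b, 100))
  expect_equal(veg_prof$rings$p_gap, 1 / veg_prof$rings$n_pixels)
  # ring width too fine for the image: inner rings have no pixels
  tiny <- band_from_matrix(matrix(100, 12, 12))
  expect_error(gap_fraction_profile(binarize(tiny, 50), ring_width_deg = 1),
               "empty zenith ring")
})

test_that("ring gap fractions track the generator's closed form", {
  img <- gen_hemiphoto(canopy_scene_params(2, image_size = 512, seed = 4))
  b <- extract_blue_band(img)
  prof <- gap_fraction_profile(binarize(b, ridler_calvard_threshold(b)))
  r <- prof$rings[prof$rings$zenith_lo == 40 & prof$rings$zenith_hi == 45, ]
  p_true <- exp(-1 / cos(42.5 * pi / 180))
  se <- sqrt(p_true * (1 - p_true) / r$n_pixels)
  expect_lt(abs(r$p_gap - p_true), 3 * se + 0.01)  # + ring-width discretization
})

test_that("fcover matches pixel shares and generator truth", {
  b <- band_from_matrix(matrix(100, 128, 128))
  expect_equal(fcover(binarize(b, 50)), 0)
  expect_equal(fcover(binarize(b, 100)), 100)

  img <- gen_hemiphoto(canopy_scene_params(2, image_size = 512, seed = 5))
  bl <- extract_blue_band(img)
  mask <- binarize(bl, ridler_calvard_threshold(bl))
  fc <- fcover(mask)
  # truth: mean vegetated probability over the 0-60 zone
  theta <- understorey:::pixel_zenith(understorey:::mask_geometry(mask))
  zone <- !is.na(theta) & theta <= 60
  p_veg <- 1 - exp(-1 / cos(pmin(theta[zone], 89) * pi / 180))
  se <- sqrt(sum(p_veg * (1 - p_veg))) / sum(zone)
  expect_lt(abs(fc / 100 - mean(p_veg)), 3 * se)
})

test_that("fcover is invariant under azimuth rotation of the mask", {
  img <- gen_hemiphoto(canopy_scene_params(1.5, image_size = 256, seed = 8))
  b <- extract_blue_band(img)
  mask <- binarize(b, ridler_calvard_threshold(b))
  rot <- mask
  # rotate the pixel grid by 90 degrees about the optical centre
  rot_m <- t(unclass(mask))[, nrow(mask):1]
  attr(rot_m, "geometry") <- attr(mask, "geometry")
  attr(rot_m, "threshold_used") <- attr(mask, "threshold_used")
  class(rot_m) <- class(mask)
  expect_equal(fcover(rot_m), fcover(mask), tolerance = 1e-9)
})

test_that("closed-form inversion is exact for the homogeneous gap model", {
  for (L in c(0.5, 1, 2, 4)) {
    mid <- seq(2.5, 57.5, by = 5)
    prof <- make_profile(exp(-0.5 * L / cos(mid * pi / 180)))
    cs <- invert_lai(prof)
    expect_equal(cs$lai_effective, L, tolerance = 1e-9)
    expect_equal(cs$clumping_index, 1)
    expect_equal(cs$lai, L, tolerance = 1e-9)
  }
  # alternative ring scheme: 10-degree rings
  mid10 <- seq(5, 55, by = 10)
  prof10 <- make_profile(exp(-0.5 * 2 / cos(mid10 * pi / 180)), width = 10)
  expect_equal(invert_lai(prof10)$lai_effective, 2, tolerance = 1e-9)
  # P == 1 everywhere: zero LAI
  expect_equal(invert_lai(make_profile(rep(1, 12)))$lai_effective, 0)
})

test_that("Lang-Xiang clumping index matches the hand-computed example", {
  # one ring, two azimuth cells with P = {e^-2, 1}
  p1 <- exp(-2); pbar <- (p1 + 1) / 2
  rings <- data.frame(zenith_lo = 0, zenith_hi = 60, theta_mid = 30,
                      n_pixels = 200, n_sky = 200 * pbar, p_gap = pbar)
  cells <- data.frame(ring = 1, cell = 1:2, n_pixels = 100,
                      n_sky = c(100 * p1, 100), p_gap = c(p1, 1))
  prof <- structure(list(rings = rings, cells = cells, ring_width_deg = 60,
                         n_azimuth_cells = 2, max_zenith = 60, n_images = 1L),
                    class = "gap_profile")
  cs <- invert_lai(prof)
  expect_equal(cs$clumping_index, log(pbar) / -1, tolerance = 1e-4)
  expect_equal(round(cs$clumping_index, 3), 0.566)
  # Jensen bound: omega <= 1 hence lai >= lai_effective
  expect_lte(cs$clumping_index, 1)
  expect_gte(cs$lai, cs$lai_effective)
})

test_that("clumped canopies yield omega < 1 and a corrected LAI nearer truth", {
  img <- gen_hemiphoto(canopy_scene_params(2, image_size = 512, clumped = TRUE,
                                           clump_shape = 1, seed = 10))
  b <- extract_blue_band(img)
  cs <- invert_lai(gap_fraction_profile(binarize(b, ridler_calvard_threshold(b))))
  expect_lt(cs$clumping_index, 1)
  expect_gt(cs$lai, cs$lai_effective)
  expect_lt(abs(cs$lai - 2), abs(cs$lai_effective - 2))
})

test_that("Monte-Carlo hemispheres recover LAI within 10% median error", {
  errs <- c()
  for (L in c(0.5, 1, 2, 4)) {
    for (s in 1:5) {
      img <- gen_hemiphoto(canopy_scene_params(L, image_size = 512,
                                               seed = 1000 * L + s))
      b <- extract_blue_band(img)
      cs <- invert_lai(gap_fraction_profile(binarize(b, ridler_calvard_threshold(b))))
      errs <- c(errs, abs(cs$lai_effective - L) / L)
    }
  }
  expect_lt(median(errs), 0.10)
})

test_that("plot pooling: idempotent for identical images, intermediate otherwise", {
  img <- gen_hemiphoto(canopy_scene_params(2, image_size = 256, seed = 12))
  single <- plot_lai(list(img))
  twelve <- plot_lai(rep(list(img), 12))
  expect_equal(twelve$lai, single$lai, tolerance = 1e-12)
  expect_equal(twelve$n_images, 12L)

  img1 <- gen_hemiphoto(canopy_scene_params(1, image_size = 256, seed = 13))
  img3 <- gen_hemiphoto(canopy_scene_params(3, image_size = 256, seed = 14))
  lo <- plot_lai(list(img1))$lai_effective
  hi <- plot_lai(list(img3))$lai_effective
  mid <- plot_lai(list(img1, img3))$lai_effective
  expect_gt(mid, min(lo, hi))
  expect_lt(mid, max(lo, hi))

  expect_error(plot_lai(list()), "empty")
  p1 <- gap_fraction_profile(binarize(extract_blue_band(img1), 100))
  p2 <- gap_fraction_profile(binarize(extract_blue_band(img3), 100),
                             ring_width_deg = 10)
  expect_error(pool_profiles(list(p1, p2)), "ring scheme")
})

test_that("hinge-angle estimator agrees with the closed form", {
  mid <- seq(2.5, 57.5, by = 5)
  prof <- make_profile(exp(-0.5 * 2 / cos(mid * pi / 180)))
  expect_equal(lai_hinge(prof), 2, tolerance = 1e-9)
})
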