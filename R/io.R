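#' Write a hemispherical image as PNG
#'
#' @param image a [hemis_image] (intensities on 0-255).
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_hemiphoto_png <- function(image, path) {
  stopifnot(inherits(image, "hemis_image"))
  png::writePNG(image$data / 255, path)
  invisible(path)
}

#' Read a PNG as a hemispherical image
#'
#' @param path PNG file.
#' @inheritParams hemis_image
#' @return a [hemis_image] with intensities on 0-255.
#' @export
read_hemiphoto_png <- function(path, center = NULL, radius = NULL,
                               lens = "equidistant", max_zenith = 90) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) stop_bad_param("expected a colour PNG")
  hemis_image(a[, , 1:3] * 255, center = center, radius = radius,
              lens = lens, max_zenith = max_zenith)
}

#' Write a thermal matrix as a headerless CSV grid
#'
#' @param thermal a [thermal_matrix] (or plain matrix).
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_thermal_csv <- function(thermal, path) {
  utils::write.table(unclass(thermal), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a synthetic scene to disk with its truth manifest
#'
#' Serializes the outputs of [gen_ground_scene()] — two-band and target
#' images as two-layer PNGs (red and near-infrared duplicated into the green
#' channel slot for viewing), the thermal matrix as CSV — together with a
#' JSON manifest of every truth parameter and the seed.
#'
#' @param scene a [gen_ground_scene()] result.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_ground_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  to_png <- function(tb, path) {
    mx <- max(tb$red, tb$nir, 1)
    arr <- array(0, c(nrow(tb$red), ncol(tb$red), 3))
    arr[, , 1] <- tb$red / mx
    arr[, , 3] <- tb$nir / mx
    png::writePNG(arr, path)
  }
  to_png(scene$twoband, file.path(dir, "twoband.png"))
  to_png(scene$target, file.path(dir, "target.png"))
  write_thermal_csv(scene$thermal, file.path(dir, "thermal.csv"))
  jsonlite::write_json(scene$truth, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
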