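#' Raster stack of co-registered bands
#'
#' A lightweight in-memory container: a named list of congruent numeric
#' matrices plus an affine geotransform (origin and pixel size). Undefined
#' pixels are `NA`.
#'
#' @param ... named matrices (bands/layers), all of identical dimension.
#' @param transform named numeric `c(xmin, ymax, res)`; row/col indices map to
#'   map coordinates as `x = xmin + (col - 0.5) * res`,
#'   `y = ymax - (row - 0.5) * res`.
#' @return an object of class `raster_stack`.
#' @export
raster_stack <- function(..., transform = c(xmin = 0, ymax = 0, res = 30)) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) && !is.matrix(layers[[1]]))
    layers <- layers[[1]]
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop_bad_param("all layers must be named")
  dims <- lapply(layers, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop_bad_param("all layers must share the same dimensions")
  structure(layers, transform = transform, class = c("raster_stack", "list"))
}

#' @export
print.raster_stack <- function(x, ...) {
  d <- dim(x[[1]])
  cat(sprintf("<raster_stack> %d x %d px, %d layer(s): %s\n",
              d[1], d[2], length(x), paste(names(x), collapse = ", ")))
  invisible(x)
}

#' @export
plot.raster_stack <- function(x, layer = 1, ...) {
  m <- x[[layer]]
  graphics::image(t(m)[, nrow(m):1], asp = nrow(m) / ncol(m),
                  main = if (is.character(layer)) layer else names(x)[layer], ...)
  invisible(x)
}

# add/replace layers, preserving class and transform
stack_set <- function(stack, ...) {
  new <- list(...)
  tr <- attr(stack, "transform")
  layers <- c(unclass(stack)[setdiff(names(stack), names(new))], new)
  do.call(raster_stack, c(layers, list(transform = tr)))
}

#' Write a raster stack to per-band files
#'
#' Writes one file per layer into `dir`: TIFF (via the tiff package, values
#' rescaled to [0,1]) when available and `format = "tiff"`, otherwise
#' headerless CSV grids. A JSON sidecar records layer names, the rescaling
#' ranges and the geotransform.
#'
#' @param stack a [raster_stack].
#' @param dir output directory (created if missing).
#' @param format `"tiff"` or `"csv"`.
#' @return invisibly, the vector of files written.
#' @export
write_stack <- function(stack, dir, format = c("csv", "tiff")) {
  format <- match.arg(format)
  stopifnot(inherits(stack, "raster_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  ranges <- list()
  for (nm in names(stack)) {
    m <- stack[[nm]]
    if (format == "tiff" && requireNamespace("tiff", quietly = TRUE)) {
      rng <- range(m, finite = TRUE)
      scaled <- (m - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
      scaled[!is.finite(scaled)] <- 0
      f <- file.path(dir, paste0(nm, ".tif"))
      tiff::writeTIFF(scaled, f)
      ranges[[nm]] <- rng
    } else {
      f <- file.path(dir, paste0(nm, ".csv"))
      utils::write.table(m, f, sep = ",", row.names = FALSE, col.names = FALSE)
    }
    files <- c(files, f)
  }
  meta <- list(layers = names(stack), transform = as.list(attr(stack, "transform")),
               format = format, value_range = ranges)
  jsonlite::write_json(meta, file.path(dir, "stack.json"), auto_unbox = TRUE)
  invisible(files)
}
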