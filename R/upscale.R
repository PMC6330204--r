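#' Screen inter-correlated predictors
#'
#' Greedy elimination: predictors are ranked by a priority order (the final
#' upscaling model features first, remaining names alphabetically); while any
#' pair of retained predictors has |Pearson r| above the threshold, the
#' lower-priority member of the worst offending pair is dropped. Constant
#' columns (undefined correlation) are removed first with a warning.
#'
#' @param table data frame of candidate predictor columns (numeric).
#' @param threshold correlation-coefficient cut-off (default 0.6).
#' @param priority character vector of predictor names ranked most- to
#'   least-preferred; names not listed rank after it, alphabetically.
#' @return character vector of retained predictor names.
#' @export
screen_predictors <- function(table, threshold = 0.6,
                              priority = c("SWIRM", "NIRM", "NIRD", "SWIRD",
                                           "NDVIMFocal", "NDVISD")) {
  preds <- names(table)
  if (length(preds) < 2L) stop_bad_param("need at least 2 candidate predictors")
  const <- vapply(preds, function(p) {
    v <- table[[p]][is.finite(table[[p]])]
    length(v) == 0L || stats::var(v) == 0
  }, logical(1))
  if (any(const)) {
    warning("removing constant predictor(s): ", paste(preds[const], collapse = ", "))
    preds <- preds[!const]
  }
  pr <- match(preds, priority)
  pr[is.na(pr)] <- length(priority) + 1L
  preds <- preds[order(pr, preds)]
  repeat {
    if (length(preds) < 2L) break
    cm <- abs(stats::cor(table[preds], use = "pairwise.complete.obs"))
    diag(cm) <- 0
    if (max(cm, na.rm = TRUE) <= threshold) break
    worst <- which(cm == max(cm, na.rm = TRUE), arr.ind = TRUE)[1, ]
    drop_idx <- max(worst)          # preds are priority-ordered; drop the later one
    preds <- preds[-drop_idx]
  }
  preds
}

#' Fit a Random-Forest canopy-structure model
#'
#' Bootstrap-aggregated regression ensemble (default 2,000 trees, per-split
#' candidate predictors `ceiling(p/3)`) linking the screened satellite
#' predictors to a plot-level canopy response, with out-of-bag variance
#' explained and permutation importances (mean increase in out-of-bag MSE,
#' with its standard error across trees).
#'
#' @param table feature table (data frame) holding predictors and the
#'   response.
#' @param response response column name (`"lai"` or `"fcover"`).
#' @param predictors character vector of predictor column names (typically
#'   from [screen_predictors()]).
#' @param ntree number of trees (default 2000).
#' @param seed integer seed for reproducible bootstraps and permutations.
#' @return an object of class `canopy_rf`.
#' @export
fit_rf <- function(table, response, predictors, ntree = 2000, seed = 1) {
  stopifnot(is.data.frame(table), response %in% names(table))
  if (length(predictors) < 1L) stop_bad_param("need at least 1 predictor")
  missing_p <- setdiff(predictors, names(table))
  if (length(missing_p) > 0)
    stop_bad_param("predictor(s) not in table: ", paste(missing_p, collapse = ", "))
  keep <- stats::complete.cases(table[c(predictors, response)])
  dat <- table[keep, , drop = FALSE]
  if (nrow(dat) < 20L) stop_bad_param("need >= 20 complete rows for fitting")
  y <- dat[[response]]
  x <- dat[predictors]
  rf <- with_seed(seed,
    randomForest::randomForest(x = x, y = y, ntree = ntree,
                               mtry = max(1L, ceiling(length(predictors) / 3)),
                               importance = TRUE, keep.forest = TRUE))
  imp <- randomForest::importance(rf, type = 1, scale = FALSE)
  imp_se <- rf$importanceSD
  ord <- order(imp[, 1], decreasing = TRUE)
  importances <- data.frame(
    predictor = rownames(imp)[ord],
    inc_mse = unname(imp[ord, 1]),
    se = unname(imp_se[ord]),   # randomForest's across-tree standard error
    stringsAsFactors = FALSE)
  structure(list(forest = rf, response = response, predictors = predictors,
                 ntree = ntree,
                 oob_variance_explained = rf$rsq[length(rf$rsq)],
                 importances = importances, n = nrow(dat), seed = seed),
            class = "canopy_rf")
}

#' @export
print.canopy_rf <- function(x, ...) {
  cat(sprintf("<canopy_rf> %s ~ %s\n", x$response,
              paste(x$predictors, collapse = " + ")))
  cat(sprintf("  %d trees, n = %d, OOB variance explained = %.1f%%\n",
              x$ntree, x$n, 100 * x$oob_variance_explained))
  print(x$importances, row.names = FALSE)
  invisible(x)
}

#' @export
predict.canopy_rf <- function(object, newdata, ...) {
  as.numeric(stats::predict(object$forest, newdata = newdata))
}

#' Predict a canopy-structure raster from a fitted forest
#'
#' Evaluates the ensemble mean per pixel over every trained predictor layer;
#' pixels where any predictor is undefined stay undefined.
#'
#' @param model a [fit_rf()] result.
#' @param stack a [raster_stack] containing every trained predictor layer.
#' @return numeric matrix of predicted LAI or FCover.
#' @export
predict_canopy_map <- function(model, stack) {
  stopifnot(inherits(model, "canopy_rf"), inherits(stack, "raster_stack"))
  missing_l <- setdiff(model$predictors, names(stack))
  if (length(missing_l) > 0)
    stop("stack is missing predictor layer(s): ",
         paste(missing_l, collapse = ", "), call. = FALSE)
  px <- as.data.frame(lapply(unclass(stack)[model$predictors], as.numeric))
  ok <- stats::complete.cases(px)
  out <- rep(NA_real_, nrow(px))
  if (any(ok))
    out[ok] <- as.numeric(stats::predict(model$forest, newdata = px[ok, , drop = FALSE]))
  matrix(out, nrow(stack[[1]]), ncol(stack[[1]]))
}

#' Map a microclimate metric from a canopy raster
#'
#' Chains a selected linear canopy-structure model onto a predicted canopy
#' raster: per pixel `intercept + coefficient * value`. Ground-NDVI outputs
#' are clipped to the index's valid range [-1, 1]; temperature outputs are
#' not clipped. Undefined pixels propagate. Additive fits are rejected — the
#' mapping uses the selected linear relation.
#'
#' @param canopy_raster numeric matrix (predicted LAI or FCover).
#' @param fit an `hq_model` of kind `"LM"` (fitted or built with
#'   [linear_model()]).
#' @return numeric matrix of the mapped metric.
#' @export
map_microclimate <- function(canopy_raster, fit) {
  stopifnot(is.matrix(canopy_raster), inherits(fit, "hq_model"))
  if (fit$kind != "LM")
    stop("microclimate mapping requires a linear fit, not a GAM", call. = FALSE)
  out <- fit$intercept + fit$coefficient * canopy_raster
  if (grepl("ndvi", tolower(fit$response)))
    out <- pmin(pmax(out, -1), 1)
  out
}

#' Write an upscaling run manifest
#'
#' Records the seed, screened predictors, model summaries and any exclusions
#' of an upscaling run as JSON, for traceability of mapped products.
#'
#' @param path output file.
#' @param seed integer seed of the run.
#' @param screened named list of retained predictors per response.
#' @param models named list of [fit_rf()] results.
#' @param notes optional character notes (exclusions, decisions).
#' @return invisibly, the path.
#' @export
write_run_manifest <- function(path, seed, screened, models, notes = character(0)) {
  manifest <- list(
    seed = seed,
    screened_predictors = screened,
    models = lapply(models, function(m) list(
      response = m$response, predictors = m$predictors, ntree = m$ntree,
      n = m$n, oob_variance_explained = m$oob_variance_explained,
      importances = m$importances)),
    notes = notes)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
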