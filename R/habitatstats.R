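#' Aggregate sample-point summaries to plot level
#'
#' Collapses per-sample region-of-interest means to one value per plot and
#' metric using the chosen statistic; excluded samples are skipped, and a plot
#' with no accepted sample for a metric gets `NA` (the metric is missing for
#' that plot, mirroring dropped plots in the field data).
#'
#' @param samples data frame with columns `plot_id`, `metric`, `value`
#'   (per-sample ROI mean) and optionally `excluded` (logical).
#' @param statistic `"mean"`, `"min"` or `"max"`, applied to the per-sample
#'   means.
#' @return wide data frame: one row per plot, one column per metric.
#' @export
aggregate_to_plot <- function(samples, statistic = c("mean", "min", "max")) {
  statistic <- match.arg(statistic)
  stopifnot(all(c("plot_id", "metric", "value") %in% names(samples)))
  plots <- unique(samples$plot_id)
  metrics <- unique(samples$metric)
  if (!is.null(samples$excluded)) samples <- samples[!samples$excluded, , drop = FALSE]
  fun <- switch(statistic, mean = mean, min = min, max = max)
  out <- data.frame(plot_id = plots, stringsAsFactors = FALSE)
  for (m in metrics) {
    out[[m]] <- vapply(plots, function(p) {
      v <- samples$value[samples$plot_id == p & samples$metric == m]
      v <- v[is.finite(v)]
      if (length(v) == 0L) NA_real_ else fun(v)
    }, numeric(1))
  }
  out
}

#' Assign treeless defaults to grassland plots
#'
#' Grassland plots have no trees, so their canopy fields are fixed by
#' definition: LAI = 0, FCover = 0, canopy NDVI (ndvi_up) = -1. Other habitats
#' pass through unchanged. A grassland row that arrives with measured canopy
#' values triggers a warning but the defaults are still applied.
#'
#' @param records data frame with columns `habitat` and any of `lai`,
#'   `fcover`, `ndvi_up`.
#' @return the records with grassland canopy fields replaced.
#' @export
assign_treeless_defaults <- function(records) {
  stopifnot("habitat" %in% names(records))
  grass <- records$habitat == "grassland"
  defaults <- c(lai = 0, fcover = 0, ndvi_up = -1)
  for (f in names(defaults)) {
    if (!f %in% names(records)) next
    if (any(grass & !is.na(records[[f]]) & records[[f]] != defaults[[f]]))
      warning(sprintf("grassland plot(s) carry measured %s; default applied", f))
    records[[f]][grass] <- defaults[[f]]
  }
  records
}

#' Pairwise Wilcoxon rank-sum tests with Bonferroni adjustment
#'
#' Two-sided rank-sum test for every pair of groups. The exact null
#' distribution is enumerated when the combined sample size of a pair is at
#' most `exact_max` and the pair has no ties; otherwise the normal
#' approximation with tie and continuity correction is used. Adjusted p-values
#' are `min(1, p * n_pairs)`.
#'
#' @param values numeric vector of observations.
#' @param groups factor/character vector of group labels, same length.
#' @param exact_max combined-n cut-off for the exact test (default 12).
#' @return symmetric matrix of Bonferroni-adjusted p-values (diagonal `NA`);
#'   raw p-values in attribute `"raw"`.
#' @export
pairwise_wilcoxon <- function(values, groups, exact_max = 12) {
  groups <- as.character(groups)
  split_vals <- split(values, groups)
  ns <- vapply(split_vals, length, integer(1))
  if (length(split_vals) < 2L) stop_bad_param("need at least 2 groups")
  if (any(ns < 2L))
    stop(sprintf("group(s) with fewer than 2 observations: %s",
                 paste(names(ns)[ns < 2], collapse = ", ")), call. = FALSE)
  labs <- names(split_vals)
  k <- length(labs)
  raw <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    x <- split_vals[[i]]; y <- split_vals[[j]]
    has_ties <- anyDuplicated(c(x, y)) > 0
    use_exact <- (length(x) + length(y) <= exact_max) && !has_ties
    p <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = use_exact, correct = TRUE)$p.value)
    if (is.nan(p)) p <- 1   # degenerate case: all values tied across the pair
    raw[i, j] <- raw[j, i] <- p
  }
  n_pairs <- k * (k - 1) / 2
  adj <- pmin(raw * n_pairs, 1)
  attr(adj, "raw") <- raw
  adj
}

new_hq_model <- function(kind, response, predictor, intercept, coefficient,
                         edf = NA_real_, adjusted_r2 = NA_real_,
                         p_values = NULL, n = NA_integer_, fit = NULL) {
  structure(list(kind = kind, response = response, predictor = predictor,
                 intercept = intercept, coefficient = coefficient, edf = edf,
                 adjusted_r2 = adjusted_r2, p_values = p_values,
                 n = n, fit = fit),
            class = "hq_model")
}

#' @export
print.hq_model <- function(x, ...) {
  cat(sprintf("<hq_model %s> %s ~ %s  (n = %s, adj R2 = %s)\n", x$kind,
              x$response, x$predictor, x$n,
              if (is.na(x$adjusted_r2)) "NA" else sprintf("%.3f", x$adjusted_r2)))
  if (x$kind == "LM")
    cat(sprintf("  intercept %.4g, coefficient %.4g\n", x$intercept, x$coefficient))
  else
    cat(sprintf("  intercept %.4g, smoother edf %.2f\n", x$intercept, x$edf))
  invisible(x)
}

#' @export
coef.hq_model <- function(object, ...) {
  if (object$kind == "LM")
    c(intercept = object$intercept, coefficient = object$coefficient)
  else c(intercept = object$intercept, edf = object$edf)
}

#' @export
predict.hq_model <- function(object, newdata, ...) {
  if (object$kind == "LM") {
    x <- if (is.data.frame(newdata)) newdata[[object$predictor]] else newdata
    object$intercept + object$coefficient * x
  } else {
    if (is.null(object$fit)) stop("GAM prediction requires the stored fit", call. = FALSE)
    x <- if (is.data.frame(newdata)) newdata[[object$predictor]] else newdata
    as.numeric(mgcv::predict.gam(object$fit, newdata = data.frame(x = x)))
  }
}

#' @export
residuals.hq_model <- function(object, ...) {
  if (is.null(object$fit)) stop("no stored fit", call. = FALSE)
  stats::residuals(object$fit)
}

#' Fit a single-predictor linear model
#'
#' Ordinary least squares of `y` on `x` with the usual adjusted R-squared
#' `1 - (1 - R2)(n - 1)/(n - 2)` and two-sided t-test p-values.
#'
#' @param y,x numeric vectors (finite, n >= 4).
#' @param response,predictor names recorded on the fit.
#' @return an `hq_model` of kind `"LM"`.
#' @export
fit_lm <- function(y, x, response = "y", predictor = "x") {
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]; x <- x[keep]
  if (length(y) < 4L) stop_bad_param("need n >= 4 finite observations")
  if (stats::var(x) == 0) stop("predictor has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  new_hq_model("LM", response, predictor,
               intercept = unname(coef(fit)[1]), coefficient = unname(coef(fit)[2]),
               adjusted_r2 = s$adj.r.squared,
               p_values = c(intercept = s$coefficients[1, 4],
                            coefficient = s$coefficients[2, 4]),
               n = length(y), fit = fit)
}

#' Fit a single-predictor additive model (penalized regression spline)
#'
#' One-dimensional thin-plate regression spline (basis dimension `k`) with
#' smoothness chosen by generalized cross-validation, via [mgcv::gam()].
#' Reports the effective degrees of freedom of the smoother; an edf near 1
#' means the penalty has shrunk the smooth to an essentially linear fit.
#'
#' @param y,x numeric vectors (finite, n >= 8).
#' @param response,predictor names recorded on the fit.
#' @param k basis dimension of the smooth (default 10).
#' @return an `hq_model` of kind `"GAM"`.
#' @export
fit_gam <- function(y, x, response = "y", predictor = "x", k = 10) {
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]; x <- x[keep]
  if (length(y) < 8L) stop_bad_param("need n >= 8 observations for the spline basis")
  k_use <- min(k, length(unique(x)) - 1L)
  fit <- mgcv::gam(y ~ s(x, k = k_use), method = "GCV.Cp")
  s <- summary(fit)
  new_hq_model("GAM", response, predictor,
               intercept = unname(coef(fit)[1]), coefficient = NA_real_,
               edf = unname(s$edf[1]), adjusted_r2 = s$r.sq,
               p_values = c(smooth = unname(s$s.table[1, 4])),
               n = length(y), fit = fit)
}

#' Select between a linear and an additive fit of the same relation
#'
#' The model with higher adjusted R-squared wins; when the two agree within
#' `tie` (default 0.005, i.e. equality at the 2-decimal reporting precision)
#' the simpler linear model is preferred.
#'
#' @param lm_fit,gam_fit `hq_model`s for the same response and predictor.
#' @param tie adjusted R-squared difference treated as a tie.
#' @return the selected `hq_model`.
#' @export
select_model <- function(lm_fit, gam_fit, tie = 0.005) {
  stopifnot(inherits(lm_fit, "hq_model"), inherits(gam_fit, "hq_model"))
  if (lm_fit$response != gam_fit$response || lm_fit$predictor != gam_fit$predictor)
    stop_bad_param("fits describe different relations")
  if (is.na(lm_fit$adjusted_r2)) return(gam_fit)
  if (is.na(gam_fit$adjusted_r2)) return(lm_fit)
  d <- gam_fit$adjusted_r2 - lm_fit$adjusted_r2
  if (abs(d) < tie || d < 0) lm_fit else gam_fit
}

#' Air-temperature interaction model for ground temperature
#'
#' OLS of `y` on `{1, x, T, x*T}`: the canopy-structure effect on ground
#' surface temperature is allowed to change with air temperature, so the
#' buffering slope steepens on hotter days.
#'
#' @param y response (ground surface temperature, degrees C).
#' @param x_struct canopy structure predictor (FCover in % or LAI).
#' @param t_air plot air temperature (degrees C).
#' @param struct_name predictor name recorded on the fit.
#' @return an `hq_interaction` with coefficients b0 (intercept), b_struct,
#'   b_T, b_interact, adjusted R-squared and per-term p-values.
#' @export
fit_interaction <- function(y, x_struct, t_air, struct_name = "fcover") {
  keep <- is.finite(y) & is.finite(x_struct) & is.finite(t_air)
  y <- y[keep]; x <- x_struct[keep]; t <- t_air[keep]
  if (length(y) < 6L) stop_bad_param("need n >= 6 observations")
  X <- cbind(1, x, t, x * t)
  if (qr(X)$rank < 4L)
    stop("degenerate design: interaction terms are collinear", call. = FALSE)
  fit <- stats::lm(y ~ x * t)
  s <- summary(fit)
  b <- unname(coef(fit))
  structure(list(b0 = b[1], b_struct = b[2], b_T = b[3], b_interact = b[4],
                 adjusted_r2 = s$adj.r.squared,
                 p_values = stats::setNames(s$coefficients[, 4],
                                            c("b0", "b_struct", "b_T", "b_interact")),
                 struct_name = struct_name, n = length(y), fit = fit),
            class = "hq_interaction")
}

#' Construct an interaction model from known coefficients
#'
#' Builds an `hq_interaction` directly from a published 4-coefficient block so
#' that [evaluate_at_tair()] and related evaluations can be applied to
#' reported models without refitting.
#'
#' @param b0,b_struct,b_T,b_interact model coefficients (intercept, structure
#'   slope, air-temperature slope, interaction).
#' @param struct_name structure predictor name.
#' @return an `hq_interaction` (no stored data fit; adjusted R-squared `NA`
#'   unless given).
#' @param adjusted_r2 optional known adjusted R-squared.
#' @export
interaction_model <- function(b0, b_struct, b_T, b_interact,
                              struct_name = "fcover", adjusted_r2 = NA_real_) {
  structure(list(b0 = b0, b_struct = b_struct, b_T = b_T,
                 b_interact = b_interact, adjusted_r2 = adjusted_r2,
                 p_values = NULL, struct_name = struct_name,
                 n = NA_integer_, fit = NULL),
            class = "hq_interaction")
}

#' @export
print.hq_interaction <- function(x, ...) {
  cat(sprintf("<hq_interaction> thermal_ground ~ %s * t_air (n = %s, adj R2 = %s)\n",
              x$struct_name, x$n,
              if (is.na(x$adjusted_r2)) "NA" else sprintf("%.3f", x$adjusted_r2)))
  print(coef(x))
  invisible(x)
}

#' @export
coef.hq_interaction <- function(object, ...) {
  c(b0 = object$b0, b_struct = object$b_struct,
    b_T = object$b_T, b_interact = object$b_interact)
}

#' Evaluate an interaction model at chosen air temperatures
#'
#' At air temperature T the model `y = b0 + b_struct x + b_T T + b_interact xT`
#' reduces to a line in the structure variable with intercept `b0 + b_T T`
#' and slope `b_struct + b_interact T`.
#'
#' @param fit an `hq_interaction`.
#' @param t_air air temperature(s) in degrees C.
#' @return data frame with columns t_air, intercept, slope (one row per
#'   temperature).
#' @export
evaluate_at_tair <- function(fit, t_air) {
  stopifnot(inherits(fit, "hq_interaction"))
  data.frame(t_air = t_air,
             intercept = fit$b0 + fit$b_T * t_air,
             slope = fit$b_struct + fit$b_interact * t_air)
}

#' Construct a linear model fit from known coefficients
#'
#' Wraps a published intercept/slope pair as an `hq_model` so that
#' [predict_change()] and [map_microclimate()] can be driven by reported
#' models.
#'
#' @param intercept,coefficient model coefficients.
#' @param response,predictor variable names.
#' @param adjusted_r2 optional known adjusted R-squared.
#' @return an `hq_model` of kind `"LM"` (no stored data fit).
#' @export
linear_model <- function(intercept, coefficient, response = "y",
                         predictor = "x", adjusted_r2 = NA_real_) {
  new_hq_model("LM", response, predictor, intercept = intercept,
               coefficient = coefficient, adjusted_r2 = adjusted_r2)
}

#' Predicted response change for a predictor change
#'
#' For a linear fit, the response change for a `delta_x` change of the
#' predictor is `coefficient * delta_x`. Additive fits have no single slope,
#' so they are rejected.
#'
#' @param fit an `hq_model` of kind `"LM"`.
#' @param delta_x predictor change.
#' @return predicted response change.
#' @export
predict_change <- function(fit, delta_x) {
  stopifnot(inherits(fit, "hq_model"))
  if (fit$kind != "LM")
    stop("no single slope for a nonlinear (GAM) fit", call. = FALSE)
  fit$coefficient * delta_x
}
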