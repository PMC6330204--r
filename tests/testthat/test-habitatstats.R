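make_samples <- function() {
  data.frame(
    plot_id = rep(c("P1", "P2"), each = 5),
    metric = "ndvi_down",
    value = c(1:5, 6:10),
    excluded = FALSE)
}

test_that("plot aggregation applies the chosen statistic and skips exclusions", {
  s <- make_samples()
  expect_equal(aggregate_to_plot(s, "mean")$ndvi_down, c(3, 8))
  expect_equal(aggregate_to_plot(s, "max")$ndvi_down, c(5, 10))
  expect_equal(aggregate_to_plot(s, "min")$ndvi_down, c(1, 6))

  s$excluded[1:2] <- TRUE
  expect_equal(aggregate_to_plot(s, "mean")$ndvi_down[1], mean(3:5))
  s$excluded[1:5] <- TRUE
  expect_true(is.na(aggregate_to_plot(s, "mean")$ndvi_down[1]))
})

test_that("treeless defaults fix grassland canopy fields and warn on conflicts", {
  rec <- data.frame(habitat = c("grassland", "forest"),
                    lai = c(NA, 3.2), fcover = c(NA, 80), ndvi_up = c(NA, 0.6))
  out <- assign_treeless_defaults(rec)
  expect_equal(out$lai, c(0, 3.2))
  expect_equal(out$fcover, c(0, 80))
  expect_equal(out$ndvi_up, c(-1, 0.6))

  conflicted <- data.frame(habitat = "grassland", lai = 2, fcover = 10, ndvi_up = 0)
  expect_warning(assign_treeless_defaults(conflicted[c("habitat", "lai")]),
                 "grassland")
  fixed <- suppressWarnings(assign_treeless_defaults(conflicted))
  expect_equal(fixed$lai, 0)
  expect_equal(fixed$fcover, 0)
  expect_equal(fixed$ndvi_up, -1)
})

test_that("pairwise Wilcoxon: exact enumeration case and Bonferroni capping", {
  p <- pairwise_wilcoxon(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(attr(p, "raw")["a", "b"], 0.1)   # 2/20 orderings as extreme
  expect_equal(p["a", "b"], 0.1)                # one pair: no adjustment

  # identical groups (all ties): adjusted p = 1
  pid <- pairwise_wilcoxon(rep(c(5, 5, 5, 5), 2), rep(c("a", "b"), each = 4))
  expect_equal(pid["a", "b"], 1)

  # 3 groups: each raw p tripled then capped at 1
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  p3 <- pairwise_wilcoxon(v, g)
  expect_equal(p3["a", "b"], min(1, attr(p3, "raw")["a", "b"] * 3))
  expect_equal(p3["a", "c"], min(1, attr(p3, "raw")["a", "c"] * 3))

  expect_error(pairwise_wilcoxon(c(1, 2, 3), c("a", "a", "b")), "fewer than 2")
})

test_that("Wilcoxon p-values equal exact enumeration for all no-tie inputs n <= 10", {
  set.seed(55)
  for (i in 1:60) {
    m <- sample(2:5, 1); n <- sample(2:5, 1)
    v <- sample(1:50, m + n)       # distinct -> no ties
    x <- v[seq_len(m)]; y <- v[-seq_len(m)]
    p <- attr(pairwise_wilcoxon(c(x, y), rep(c("a", "b"), c(m, n))), "raw")["a", "b"]
    expect_equal(p, wilcoxon_enum_oracle(x, y), tolerance = 1e-12,
                 label = sprintf("case %d (m=%d, n=%d)", i, m, n))
  }
})

test_that("linear fit: exact recovery, adjusted R2, degenerate predictors", {
  x <- c(1, 2, 3, 4, 5)
  f <- suppressWarnings(fit_lm(2 + 3 * x, x))
  expect_equal(f$intercept, 2, tolerance = 1e-12)
  expect_equal(f$coefficient, 3, tolerance = 1e-12)
  expect_equal(f$adjusted_r2, 1, tolerance = 1e-9)
  expect_lt(max(abs(residuals(f))), 1e-9)

  fc <- suppressWarnings(fit_lm(rep(4, 5), x))
  expect_equal(fc$coefficient, 0, tolerance = 1e-12)

  expect_error(fit_lm(1:5, rep(2, 5)), "zero variance")
  expect_error(fit_lm(1:3, 1:3), "n >= 4")

  # adjusted R2 definition check against the closed form
  set.seed(77); xx <- rnorm(20); yy <- 1 + 0.5 * xx + rnorm(20)
  fl <- fit_lm(yy, xx)
  r2 <- cor(yy, xx)^2
  expect_equal(fl$adjusted_r2, 1 - (1 - r2) * 19 / 18, tolerance = 1e-10)
})

test_that("slope confidence intervals cover simulation truth at nominal rate", {
  hits <- 0L
  for (s in 1:200) {
    p <- plot_sim_params(n_plots = 34, coef_thermal = c(27.4, -1.19),
                         noise_sd = c(thermal = 0.5, ndvi = 0.1), seed = s)
    d <- assign_treeless_defaults(gen_plot_dataset(p))
    f <- fit_lm(d$thermal_ground, d$lai)
    ci <- confint(f$fit)["x", ]
    if (ci[1] <= -1.19 && -1.19 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 180L)   # >= 90% of 200 replicates
})

test_that("additive fit: edf near 1 on linear data, wins on curved data", {
  # near-linear data (tiny noise keeps the GCV criterion well-posed):
  # the penalty shrinks the smooth to an essentially linear fit
  set.seed(1)
  x <- seq(0, 1, length.out = 40)
  y <- 2 + 3 * x + rnorm(40, sd = 0.01)
  g <- fit_gam(y, x)
  expect_lt(abs(g$edf - 1), 0.1)
  l <- fit_lm(y, x)
  expect_lt(abs(g$adjusted_r2 - l$adjusted_r2), 0.01)

  set.seed(88)
  xq <- seq(-1, 1, length.out = 50)
  yq <- xq^2 + rnorm(50, sd = 0.05)
  expect_gt(fit_gam(yq, xq)$adjusted_r2, fit_lm(yq, xq)$adjusted_r2)

  # constant response: no signal, no explained variance
  gc <- fit_gam(rep(2, 20), seq_len(20))
  expect_lte(gc$adjusted_r2, 0)
  expect_error(fit_gam(1:7, 1:7), "n >= 8")
})

test_that("model selection prefers higher adjusted R2 with ties to the LM", {
  lm_fit <- linear_model(1, 2, "thermal_ground", "fcover", adjusted_r2 = 0.51)
  gam_fit <- structure(list(kind = "GAM", response = "thermal_ground",
                            predictor = "fcover", intercept = 1,
                            coefficient = NA, edf = 2, adjusted_r2 = 0.51,
                            p_values = NULL, n = 34, fit = NULL),
                       class = "hq_model")
  expect_equal(select_model(lm_fit, gam_fit)$kind, "LM")    # tie -> simpler
  gam_fit$adjusted_r2 <- 0.513
  expect_equal(select_model(lm_fit, gam_fit)$kind, "LM")    # within 0.005 -> tie
  gam_fit$adjusted_r2 <- 0.56
  expect_equal(select_model(lm_fit, gam_fit)$kind, "GAM")
  lm_fit$adjusted_r2 <- 0.3; gam_fit$adjusted_r2 <- 0.2
  expect_equal(select_model(lm_fit, gam_fit)$kind, "LM")
  # LM not significant (no adjusted R2): the GAM is reported
  lm_fit$adjusted_r2 <- NA_real_
  gam_fit$adjusted_r2 <- 0.39
  expect_equal(select_model(lm_fit, gam_fit)$kind, "GAM")
  other <- linear_model(0, 1, "ndvi_down", "lai", adjusted_r2 = 0.2)
  expect_error(select_model(other, gam_fit), "different relations")
})

test_that("interaction model: exact coefficient recovery and permutation invariance", {
  b <- c(2.074357, 0.155010, 0.887836, -0.007211)
  set.seed(99)
  fc <- runif(34, 0, 100); t_air <- runif(34, 21, 29)
  y <- b[1] + b[2] * fc + b[3] * t_air + b[4] * fc * t_air
  f <- suppressWarnings(fit_interaction(y, fc, t_air))
  expect_equal(unname(coef(f)), b, tolerance = 1e-9)

  perm <- sample(34)
  f2 <- suppressWarnings(fit_interaction(y[perm], fc[perm], t_air[perm]))
  expect_equal(coef(f2), coef(f), tolerance = 1e-9)

  expect_error(fit_interaction(y[1:5], fc[1:5], t_air[1:5]), "n >= 6")
  expect_error(fit_interaction(y, fc, rep(25, 34)), "collinear|degenerate")
})

test_that("null interaction truth is not significant in most replicates", {
  hits <- 0L
  for (s in 1:100) {
    p <- plot_sim_params(n_plots = 34,
                         coef_interaction = c(20, -0.03, 0.2, 0),
                         noise_sd = c(thermal = 1, ndvi = 0.1), seed = 400 + s)
    d <- assign_treeless_defaults(gen_plot_dataset(p))
    f <- fit_interaction(d$thermal_ground, d$fcover, d$t_air)
    if (f$p_values[["b_interact"]] >= 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("interaction evaluation reduces to intercept/slope lines in T_air", {
  fm <- interaction_model(2.074357, 0.155010, 0.887836, -0.007211)
  ev <- evaluate_at_tair(fm, c(21, 25))
  expect_equal(round(ev$intercept[1], 1), 20.7)
  expect_equal(round(ev$slope[2], 4), round(-0.02527, 4))
  # zero interaction: slope independent of T
  f0 <- interaction_model(1, 0.5, 0.2, 0)
  ev0 <- evaluate_at_tair(f0, c(10, 30))
  expect_equal(ev0$slope, c(0.5, 0.5))
})

test_that("marginal-change predictions follow the linear slope", {
  f <- linear_model(27.6, -0.06, "thermal_ground", "fcover")
  expect_equal(predict_change(f, 20), -1.2)
  expect_equal(predict_change(f, 0), 0)
  f2 <- linear_model(27.4, -1.19, "thermal_ground", "lai")
  expect_equal(predict_change(f2, 1), -1.19)
  gam_fit <- structure(list(kind = "GAM", response = "y", predictor = "x",
                            intercept = 0, coefficient = NA, edf = 2,
                            adjusted_r2 = 0.5, p_values = NULL, n = 20,
                            fit = NULL), class = "hq_model")
  expect_error(predict_change(gam_fit, 1), "GAM|nonlinear")
})

test_that("full pipeline on simulated plots recovers coefficients within CIs", {
  # interaction truth + realistic noise; 60 seeded replicates
  b <- c(2.074357, 0.155010, 0.887836, -0.007211)
  hits <- matrix(0L, 60, 4)
  for (s in 1:60) {
    p <- plot_sim_params(n_plots = 34, coef_interaction = b,
                         noise_sd = c(thermal = 0.5, ndvi = 0.1), seed = 700 + s)
    d <- assign_treeless_defaults(gen_plot_dataset(p))
    f <- fit_interaction(d$thermal_ground, d$fcover, d$t_air)
    ci <- confint(f$fit)
    hits[s, ] <- as.integer(ci[, 1] <= b & b <= ci[, 2])
  }
  expect_gte(min(colMeans(hits)), 0.9)
})
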