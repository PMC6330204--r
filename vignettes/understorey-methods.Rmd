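---
title: "Methods: from fisheye images to landscape microclimate maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from fisheye images to landscape microclimate maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(understorey)
```

This vignette is the package's account of its own science: the models it
implements, the assumptions behind them, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the places where the
design was genuinely open and a choice had to be made.

## 1. Canopy structure from hemispherical photographs

### The gap model and its inversion

Everything rests on the classical gap-fraction model for a horizontally
homogeneous canopy: a ray at zenith angle $\theta$ traverses unobstructed
with probability

$$P(\theta) = \exp\!\left(-\,\frac{G(\theta)\,L}{\cos\theta}\right),$$

where $L$ is the plant area index (PAI: leaves plus stems and branches —
optical methods cannot separate them, and masking woody parts would bias $L$
low) and $G$ is the mean projection of unit foliage area on the plane normal
to the view direction. We assume a spherical leaf-angle distribution, for
which $G = 0.5$ at all angles. Under this model every zenith ring of a binary
sky/vegetation mask supplies an unbiased ring statistic
$-\ln \bar P(\theta)\cos\theta = G L$, so the inversion in `invert_lai()` is
the pixel-count-weighted mean of that statistic over all rings, divided by
$G$. The estimator is exact (to floating point; the closed-form tests assert
1e-9) whenever the data really come from the model, uses all rings rather
than a single angle, and needs no iterative fitting. A single-ring
hinge-angle estimator at 57.5° — where $G$ is nearly independent of the leaf
angle distribution — is provided (`lai_hinge()`) as a cross-check only.

Real canopies are clumped: foliage aggregates in crowns, so the
scene-averaged gap fraction overestimates $P$ and effective LAI
underestimates truth. The Lang–Xiang correction compares the log of the
ring-mean gap fraction with the mean of log cell-wise gap fractions over
azimuth cells:

$$\Omega = \frac{\ln \bar P}{\overline{\ln P_{\mathrm{cell}}}} \le 1
\quad\text{(Jensen's inequality)}, \qquad L = L_{\mathrm{eff}} / \Omega.$$

Ring-wise $\Omega$ values are combined by pixel-count weights. A ring with no
vegetation carries no clumping information and contributes $\Omega = 1$.
Values outside $(0, 1]$ (possible only through sampling noise) are clipped to
1 with a warning.

### Numerical choices

* **Field of view 0–60°.** Rings cover $(0°, 60°]$; beyond 60° pixels near
  the horizon mix sky and vegetation and would corrupt the profile. FCover is
  defined over the same zone for consistency; a nadir-cone definition is
  available through the `max_zenith` argument.
* **Ring width 5°, 8 azimuth cells.** Twelve rings give enough angular
  resolution for the weighted inversion while keeping thousands of pixels per
  ring at the default 512-pixel image size; eight cells per ring is the
  coarsest division that still detects crown-scale clumping. Both are
  configurable.
* **Saturation guard.** A fully vegetated ring or cell has $\bar P = 0$ and
  an undefined logarithm; it is replaced by $1/n_{\mathrm{pixels}}$, the
  smallest gap fraction the sample could have resolved — standard
  gap-fraction practice, and the value the tests assert.
* **Isodata threshold.** The Ridler–Calvard iteration starts at the global
  mean and stops when the update falls below 0.01 intensity units (cap 100
  iterations). The fixed point is invariant (equivariant) under affine
  intensity maps, which the property tests exercise; agreement with an
  exhaustive scan of all 256 candidate 8-bit cuts is asserted on random
  bimodal images.
* **Plot pooling.** Plot-level LAI sums ring-wise sky/total pixel counts
  across a plot's images and inverts once. Averaging gap fractions *before*
  the log transform is deliberate: the log of a mean is not the mean of logs,
  and pooling is what makes twelve images of the same stand equivalent to one
  larger sample (the pooling-idempotence test).

### Open points

The inversion's exact parameterization (leaf-angle model, ring scheme) in
the original canopy-analysis software chain is not published beyond the
0–60° restriction, so numerical agreement with that software is not claimed;
the implementation here is defined entirely by the formulas above and is
validated against its own closed form and Monte-Carlo truth. Likewise
whether published "FCover" is 0–60° cover or a nadir cone is ambiguous; the
0–60° definition is the default because it matches the stated field-of-view
restriction.

## 2. Field NDVI and thermal processing

Two-band images are calibrated by a single multiplicative gain per band,
$k = \rho_{\mathrm{target}} / \mathrm{DN}_{\mathrm{target}}$, because the
standard ground-target procedure provides one reference; a two-target affine
variant (`calibrate_affine()`) is included since a gain-only model cannot
remove a sensor offset. NDVI is the usual normalized difference; a zero
denominator is undefined rather than an error. Thermal snapshots are
headerless CSV grids (configurable delimiter); their region of interest is
fixed at 150 × 150 cells, matching the standard sample extent, and any other
thermal ROI size is rejected. ROI statistics use finite values only, with
the sample (n−1) standard deviation.

The exclusion rule for badly calibrated NDVI samples — mean outside
$[-1, 1]$ or more than 5 % of pixels outside — quantifies "non-sensible
calibration". The 5 % figure is this package's choice (recorded in the
validation output); a genuinely mis-calibrated image fails it by a wide
margin, while a handful of specular pixels does not.

## 3. Plot statistics

* **Aggregation** collapses per-sample ROI *means* to plots by mean, min or
  max. Min/max are extremes of per-sample means, not pixel-level extremes —
  the plot is the statistical unit, samples are its replicates.
* **Treeless defaults**: grassland plots have no trees by definition, so
  LAI = 0, FCover = 0 and canopy NDVI = −1 are assigned, letting grassland
  anchor the open end of the structure gradient instead of being dropped.
* **Wilcoxon tests** are two-sided with Bonferroni adjustment
  ($p_{\mathrm{adj}} = \min(1, p \cdot n_{\mathrm{pairs}})$). The exact null
  is enumerated when a pair's combined $n \le 12$ with no ties; otherwise the
  normal approximation with tie and continuity correction is used. A fully
  tied pair is degenerate and reported as $p = 1$. Tests compare against an
  independent enumeration oracle over all labelings.
* **LM vs GAM.** Both a straight line and a penalized thin-plate spline
  (basis dimension 10, smoothness by GCV) are fit to each relation; the
  higher adjusted R² wins, and a difference below 0.005 — equality at
  2-decimal reporting precision — goes to the simpler linear model. GCV on
  *exactly* noise-free data is ill-posed (any smoothness fits perfectly), so
  the linearity tests add tiny noise; with any realistic noise the penalty
  drives the smoother's effective degrees of freedom to 1 on linear truth.
* **Interaction model.** `fit_interaction()` is OLS on
  $\{1, x, T, xT\}$; `evaluate_at_tair()` reduces it to the
  intercept/slope line $b_0 + b_2 T$, $b_1 + b_3 T$ used to report
  temperature-dependent buffering. The model is exact linear algebra on four
  numbers, so published coefficient blocks can be wrapped directly with
  `interaction_model()` and evaluated without refitting.

## 4. Satellite predictors and upscaling

* **QA masking** keeps only the clear-condition codes (322, 386, 834, 898,
  1346); water codes and every unrecognized code are set undefined in all
  bands. Masking is idempotent.
* **GLCM textures.** The "90° shift" is interpreted as the vertical
  neighbour offset with symmetric accumulation — the convention of the
  widely used texture package in this field. Quantization to 64 equal-width
  levels is *global* over the band's finite range, not per-window, so
  textures are comparable across the scene. MEAN and DISSIMILARITY are
  expectation and mean absolute level difference of the window's
  co-occurrence distribution; a brute-force double-loop counter is the test
  oracle.
* **Focal window.** A nominal "8-pixel" moving window has no centre pixel;
  the nearest odd window, 9 × 9, is the default (configurable), and the
  choice is recorded here rather than hidden.
* **Predictor screening** removes, from each pair with $|r| > 0.6$, the
  predictor ranked lower in a priority order headed by the features of the
  final published upscaling models (SWIRM, NIRM, NIRD, SWIRD, NDVIMFocal,
  NDVISD), then alphabetical. The threshold is read as a correlation
  coefficient: screening at a *p-value* of 0.6 would be meaningless.
* **Random Forest.** 2,000 trees, `mtry = ceiling(p/3)`, permutation
  importances with their across-tree standard errors, skill reported as
  out-of-bag variance explained. OOB validation is internal
  cross-validation: each tree is tested on the samples its bootstrap left
  out.
* **Map chaining** applies the *selected linear* structure–microclimate
  model per pixel. Ground-NDVI maps are clipped to the index's valid
  $[-1, 1]$; temperature maps are not clipped (there is no physical bound to
  enforce). Additive fits are rejected: a GAM has no single slope, and
  tabulated-smooth mapping is out of scope. The with-grassland linear fits
  are the default chain because grassland anchors the open-canopy end of the
  gradient that upscaled maps must cover.

## 5. The synthetic-data generator

The generator exists so that every stage has inputs with *known truth*:

* `gen_hemiphoto()` draws each in-footprint pixel as an independent
  Bernoulli sky/vegetation trial at the closed-form gap probability of its
  zenith angle (equidistant lens by default; equisolid selectable), renders
  sky bright and foliage dark in the blue channel with mild Gaussian sensor
  noise. A clumped mode multiplies per-sector foliage density by
  gamma-distributed factors with mean one, producing $\Omega < 1$ while
  keeping the sector-mean density at the target LAI — exactly the
  heterogeneity the Lang–Xiang correction removes.
* `gen_ground_scene()` encodes a chosen NDVI into band reflectances through
  fixed per-band gains and produces the matching target image, so the full
  calibration chain recovers the truth by construction; the thermal matrix
  has the stated mean and spread.
* `gen_plot_dataset()` emulates a 34-plot campaign: habitats allocated by
  largest remainder to the stated proportions (6 grassland, 1 bush, 11 edge,
  11 forest, 1 woodland, 4 plantation), per-habitat LAI ranges, cover tied
  to LAI by a light-extinction curve, responses from the stated linear or
  interaction truth plus Gaussian noise. The default truth coefficients
  (27.4, −1.19 for temperature against LAI; 0.57, −0.09 for ground NDVI) and
  air temperatures uniform on 21–29 °C are the package's standing study
  conditions; residual standard deviations (2.0 °C, 0.15 NDVI) were chosen
  once to give the plot-scale explained variance typical of such campaigns
  (adjusted R² near 0.5 for temperature) and are not tuned per analysis.
  Grassland rows carry `NA` canopy fields so the defaults rule is exercised
  downstream.
* `gen_landsat_scene()` builds a smooth random LAI field (Gaussian-blurred
  white noise rescaled to 0–6), pushes it through a monotone forward model
  (NIR rising, RED/SWIR1 falling with LAI, saturating exponentials), adds
  reflectance noise, and scatters QA codes (80 % clear / 10 % water / 10 %
  other by default).

Every generator is a pure function of its seed and restores the caller's
RNG state.

**What passing tests do and do not show.** The generators share the
*functional form* of the models being estimated (that is what makes exact
recovery tests possible), so green tests demonstrate correctness of the
implementation, not robustness to real-world violations: no penumbra or
mixed pixels in the fisheye scenes, no within-plot spatial autocorrelation,
no emissivity variation in the thermal matrices, no sensor PSF, vignetting
or georeferencing error in the rasters. Conclusions about field performance
still require field validation.

## 6. Problem sizes and determinism

The test suite and the property checks run at deliberately desk-friendly
sizes chosen as the smallest at which the statistical assertions are stable:
hemispherical images at 512 px (128–256 px for pure plumbing checks),
Monte-Carlo recovery over LAI ∈ {0.5, 1, 2, 4} with several seeds each,
100-iteration oracle sweeps for thresholding/GLCM, 200 seeded replicates for
confidence-interval coverage, and a 100 × 100 scene with 150 training pixels
for the end-to-end raster chain (unit tests use 300–500 trees; the
production default stays 2,000). All stochastic tests fix their seeds; the
acceptance script takes its seed on the command line.

## 7. Known limitations

* The gap-model inversion assumes the canopy fills the whole hemisphere
  homogeneously within rings; isolated trees against open sky violate this
  and bias $L$ low even with the clumping correction.
* Single-target calibration cannot correct a sensor offset; use the affine
  variant when a dark target is available.
* The thermal chain treats camera output as calibrated surface temperature;
  emissivity differences between litter, soil and grass are not adjusted
  for.
* Raster handling is in-memory and single-scene: mosaicking, reprojection
  and tiling are out of scope, and outputs are plain per-band files rather
  than georeferenced GeoTIFF.
* The Wilcoxon exact path enumerates only tie-free small samples, matching
  standard practice; heavily tied small samples fall back to the corrected
  normal approximation.
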