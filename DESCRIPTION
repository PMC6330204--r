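Package: understorey
Title: Canopy Structure and Below-Canopy Habitat Quality from Field and Satellite Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving habitat-quality metrics of the forest understorey
    from ground-based imagery and upscaling them with satellite data. Implements
    gap-fraction analysis of hemispherical canopy photographs (Ridler-Calvard
    isodata thresholding, zenith-ring gap fractions restricted to 0-60 degrees,
    clumping-corrected plant area index and fractional cover), calibration of
    two-band (red/near-infrared) ground cameras against reflectance targets,
    region-of-interest summaries of ground NDVI and thermal-camera temperature
    matrices, plot-level statistical models linking canopy structure to ground
    surface temperature and ground greenness (linear and additive models,
    air-temperature interactions), Landsat-style predictor engineering (pixel-QA
    masking, NDVI/MSAVI2/EVI2, grey-level co-occurrence textures, focal
    statistics) and Random-Forest upscaling of leaf area index and fractional
    cover to landscape maps of ground temperature and greenness. A seeded
    synthetic-data generator emulates every input so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    mgcv,
    randomForest,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    tiff,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
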