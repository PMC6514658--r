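Package: phenorgb
Title: Plot-Level RGB Vegetation Indices and Trial Analysis for Field Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: High-throughput plant phenotyping from consumer RGB cameras at
    ground or UAV level. Converts 8-bit canopy images into HSI, CIELab and
    CIELuv colour planes and computes plot-level vegetation indices (green
    area, greener green area, crop senescence index, TGI, NGRDI, and the
    CIE-colour-space normalized-difference indices NDLab and NDLuv). Includes
    orthomosaic plot cropping, camera quality assurance (ColorChecker
    calibration check, vignetting transects with hue-based soil filtering),
    trial-level agronomy (grain yield, yield loss index, senescence, quartile
    yield groups and cross-treatment overlap), correlation and stepwise-AIC
    multivariate yield models with simplified-formula reduction, and a
    synthetic canopy-scene and trial generator with ground-truth masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    stats,
    utils,
    MASS,
    png,
    tiff,
    jpeg
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
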