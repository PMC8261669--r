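Package: floodscore
Title: UAV Image Features for Scoring Soybean Flooding Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for estimating five-level soybean
    flooding injury scores (FIS) from UAV multispectral and thermal imagery of
    single-row breeding plots. Generates synthetic per-plot scenes at three
    flight heights (20/50/80 m) with flooding-injury-dependent canopy
    structure, converts raw digital numbers to reflectance by panel-based
    (unified-factor) or max-min calibration, removes soil/shadow background by
    a stepwise color-space procedure and K-means thermal clustering, extracts
    the five plot-level features (canopy temperature, NDVI, area, width,
    length), compares groups by one-way ANOVA with Tukey HSD letters, and
    classifies FIS with a 5-10-1 feedforward network trained by
    Levenberg-Marquardt least squares whose continuous output is binned to
    five levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    tiff,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    minpack.lm,
    multcomp,
    knitr,
    rmarkdown
Config/testthat/edition: 3
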