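Package: equitherm
Title: Texture Analysis of Equine Thermograms and Biomarker Slope Parallelism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for advanced texture analysis of pseudo-color infrared
    thermograms of the equine thoracolumbar region across repeated exercise.
    Decomposes 8-bit RGB thermograms into the twelve components of the RGB,
    YUV, YIQ and HSB color models, applies gray-level normalization, and
    extracts 88 texture features from eight approaches (histogram statistics,
    gradient map, causal autoregressive model, Gabor transform, histogram of
    oriented gradients, gray-level run-length matrix, and symmetric and
    asymmetric gray-level co-occurrence matrices) per region of interest,
    alongside conventional maximal and mean region temperatures. Implements
    the statistical pipeline that routes samples by normality, compares
    before/after-exercise and across-repetition measurements, and selects
    texture features whose across-repetition regression slopes are parallel
    to blood biomarkers of exercise effect (ANCOVA slope-equality testing
    with pooled slopes and intercepts). Includes a synthetic study generator
    (temperature fields, rainbow-palette rendering, region masks, biomarker
    panels) with the coupling structure the selection procedure is designed
    to recover, so the full pipeline is testable without camera data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    MASS,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
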