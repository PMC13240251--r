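Package: spadspec
Title: Leaf SPAD Estimation from Hyperspectral Reflectance in Maize
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calibrating leaf SPAD (relative chlorophyll) against
    hyperspectral leaf reflectance (325-1075 nm at 1 nm), organised as the
    chemometrics workflow used in maize phenotyping: K-means and Monte-Carlo
    PLSR outlier screening with paired exclusion, Savitzky-Golay / SNV /
    detrend / MSC preprocessing chains, 21 nominal-band vegetation indices,
    Pearson correlation screening with magnitude classes, deterministic SPXY
    calibration/validation partitioning, single-index function regression
    (linear, quadratic, exponential, power) and multi-index random-forest
    regression, evaluated by R-squared, RMSE and RPD with capability classes.
    Includes a synthetic leaf-spectrum generator with planted outliers and
    retained ground truth so every stage can be exercised and benchmarked
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    signal,
    minpack.lm,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite
Config/testthat/edition: 3
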