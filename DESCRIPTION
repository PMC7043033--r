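Package: leafskew
Title: Skewed-Distribution Colour Descriptors and SPAD Models for Leaf Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for describing leaf colour from masked RGB photographs with
    skewed-distribution histogram parameters (mean, median, mode, skewness,
    kurtosis per red, green, blue and gray channel), mean-based colour indices,
    normality testing of colour-gradation samples (Lilliefors with
    Monte-Carlo-calibrated critical values, Jarque-Bera), correlation tables
    with significance stars, Duncan multiple-range letter displays, and
    fitting/evaluation of SPAD chlorophyll association models (stepwise linear
    regression, single-term Fourier curve, bivariate polynomial surface),
    including published coefficient sets as ready-made predictors. A synthetic
    leaf-image generator with analytically known channel moments supports
    fully reproducible validation without any image download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jpeg,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    nortest
Config/testthat/edition: 3
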