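Package: maizeLNC
Title: Corn Leaf Nitrogen Content Estimation from Canopy Hyperspectral Reflectance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Workflow for estimating corn leaf nitrogen content (LNC, % dry
    mass) from canopy hyperspectral reflectance (350-2500 nm). Provides
    Savitzky-Golay smoothing, first-derivative spectra and water-vapor band
    masking; continuum-removal position features (depth, area, normalized
    depth over absorption and reflection regions, plus edge and peak
    parameters); a registry of 34 vegetation indices; successive projections
    algorithm (SPA) variable screening; partial least squares and random
    forest regression with R2/RMSE/NRMSE evaluation; and a
    nitrogen-parameterized synthetic canopy spectra generator so the whole
    pipeline is testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    mixOmics,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
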