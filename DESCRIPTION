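Package: speckleclass
Title: Unsupervised Classification of Transient Decorrelation Events from
    Parallelized Single-Photon Speckle Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates and analyses diffuse correlation spectroscopy (DCS)
    measurements acquired with a single-photon avalanche diode (SPAD) array
    behind a bundle of multimode detection fibers. Provides a synthetic-data
    generator for photon-count frame streams produced by speckle fields
    decorrelating through a dynamic turbid medium, per-pixel and per-fiber
    intensity autocorrelation (g2) estimators with look-up-table pixel
    grouping, and an unsupervised deep clustering network (stacked
    autoencoder trained jointly with a k-means objective) that classifies
    transient decorrelation events without labels. Includes classical
    embedding baselines, permutation-matched clustering accuracy, and an
    experiment runner for letter, circle and flow-tube perturbation
    benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
VignetteBuilder: knitr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
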