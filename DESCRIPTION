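Package: carpetFCS
Title: Pair-Correlation Carpet, FCS and Number-and-Brightness Analysis of
    Line-Scan Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-correlation spectroscopy toolkit for quantifying
    intracellular transport from confocal line-scan time series
    ("carpets") and image stacks. Computes per-column autocorrelation
    (ACF) and pair correlation functions (pCF) on a quasi-logarithmic
    multi-tau lag grid, fits single-component FCS diffusion models with
    chi-square validation and fast/slow classification, performs
    number-and-brightness (N&B) moment analysis under dual fast/slow
    segmentation schemes, partitions pixel columns into
    cytoplasm/nuclear-envelope/nucleoplasm zones around a detected
    lamina, runs distance-transform-seeded 3D watershed particle
    segmentation with distance-from-nucleus binning, and produces
    two-channel cross-correlated pCF amplitude maps for co-transport
    detection. A Brownian-dynamics line-scan simulator with a
    semi-permeable barrier provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    ggplot2,
    rlang,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
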