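Package: dfa2d
Title: Two-Dimensional Detrended Fluctuation Analysis for Image Texture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Fractal texture characterization of raster images by
    two-dimensional detrended fluctuation analysis (2D DFA): grayscale
    conversion, row/column mean-centered integration, least-squares plane
    detrending over disjoint square segments, the fluctuation function
    F(s), and scaling exponents (global alpha, short-range alpha1 over
    scales 4-11, long-range alpha2 above 12) fitted on the log-log
    fluctuation curve.  Includes the classical one-dimensional DFA as a
    reference implementation, generators for synthetic benchmark images
    (tiled circle/square shape grids, fractional Brownian surfaces,
    i.i.d. noise), one-way ANOVA with Tukey-Kramer group comparison of
    exponents, batch analysis over image manifests, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
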