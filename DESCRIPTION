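Package: cmradiomics
Title: Robustness of Radiomic Features from Quantitative Cardiac T1/T2 Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how image preprocessing affects 2D radiomic
    features estimated from quantitative cardiac magnetic resonance T1 and T2
    maps. Provides a seeded synthetic generator of single-slice relaxation-time
    maps with annular myocardial regions of interest; cubic B-spline grid
    resampling, fixed-bin-width gray-level discretization and a set of spatial
    filters (undecimated Daubechies-3 wavelets, gradient magnitude, square,
    square root); a 98-feature 2D radiomic engine (shape, first order, GLCM,
    GLRLM, GLSZM, GLDM, NGTDM); and robustness statistics: two-way mixed
    single-rater absolute-agreement intraclass correlation, coefficients of
    variation, and repeated-measures correlation with Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
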