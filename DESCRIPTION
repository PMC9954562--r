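Package: spheromorph
Title: Spheroid Morphometry and Growth-Law Analysis for 3D Tumor Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of multicellular spheroids grown in 3D
    hydrogel cultures and of segmented tumor volumes. Provides synthetic-data
    generators with exact geometric ground truth (Fourier-perturbed spheroid
    boundaries, band-limited random tumor surfaces, exponential cell-count
    series), 2D morphometry (area, Crofton perimeter, circularity, equivalent
    and Feret diameter), 3D sphericity from voxel masks via smoothed
    isosurface triangulation, exponential growth-law fitting with automatic
    window selection, compactness scoring of observed size distributions
    against spherical-growth predictions, and the variance (Levene quadratic)
    and rank (Mann-Whitney) tests used to compare shape regularity across
    size strata. Tibble-first API with tidy(), glance() and autoplot()
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tiff,
    withr,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
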