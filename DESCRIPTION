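Package: chromaseg
Title: Histogram-Seeded Tissue Segmentation and Luminance-Matched
    Colorization of Gray Brain MR Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-phase nearest-centroid segmentation of T2-weighted brain
    MR volumes into gray matter, white matter and cerebrospinal fluid, with
    cluster centroids selected automatically from per-plane histogram peaks
    inside anatomically prescribed intensity ranges (hard labels and graded
    soft memberships). Also provides a luminance-matched CIELAB colorization
    that transfers chromaticity from a visible-spectrum palette onto any
    grayscale medical image while preserving the original luminance, a
    volume-based Jaccard coefficient for comparing segmentations, and a
    seeded T2-like phantom generator with ground-truth labels for testing
    every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
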