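Package: tortr
Title: Curvature-Based Arterial Tortuosity from 3D Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline that turns a labeled 3D artery
    segmentation (NIfTI-1) into curvature-based tortuosity metrics.
    The target label is binarized, skeletonized to a one-voxel-wide
    medial line, endpoints are detected by 26-neighbourhood counting,
    the centerline is ordered by graph traversal, and a unit-speed
    (arc-length parametrized) cubic B-spline is fit so that curvature
    can be evaluated analytically from first and second derivatives.
    Reports arc-over-chord ratio, total curvature, mean squared
    curvature and arc-length-normalized RMS curvature per vessel,
    together with the spline RMSE as a fit-quality indicator. Ships a
    phantom generator (helices, arcs, lines, voxelized tubes, seeded
    noise at controlled SNR) with closed-form ground truth so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
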