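Package: vascnet
Title: Quantitative Morphometry of Segmented Vascular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pre-segmented 2D and 3D vasculature
    volumes. Extracts single-voxel centerlines by topology-preserving
    parallel thinning, estimates per-centerline-point radii with a
    modified Euclidean distance transform that measures to the faces of
    axis-aligned background voxels, builds an undirected centerline graph
    under 26-connectivity, removes spuriously labeled branchpoints by
    radius-weighted clique filtering, prunes short isolated and endpoint
    segments, and reports segment-level (spline length, tortuosity,
    radius statistics, lateral surface area, volume) and network-level
    features. Includes atlas-annotation region-of-interest analysis and a
    synthetic phantom generator with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    png,
    Rcpp,
    RNifti,
    splines,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
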