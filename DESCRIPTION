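Package: tesserate
Title: Morphometry, Topology and Growth Simulation for Tessellated Cartilage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying tessellated cartilage, the mosaic of small
    mineralized tiles (tesserae) that covers the cartilaginous skeleton of
    sharks and rays. Provides synthetic phantom generation (hard-core seed
    point processes, planar/spherical/cylindrical Voronoi tessellations,
    Goldberg polyhedra, voxelized shell phantoms with full ground truth),
    instance segmentation of grayscale shell volumes (thresholding, binary
    cleaning, exact Euclidean distance transforms, hierarchical watershed
    with persistence merging, scriptable label proofreading), region
    adjacency graph construction and editing, per-tessera morphometrics
    (thickness, width, volume, plane-based area, surface curvature from
    smoothed meshes), tessellation-level statistics (polygon-class
    frequencies, Euler characteristic, hexagonal deficiency, peak-rescaled
    self-similar size distributions, allometric log-log regressions), and a
    two-scenario tessellation growth simulator (constant-rate versus
    gap-proportional mineral apposition on an expanding substrate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deldir,
    polyclip,
    RANN,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    tiff,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    spatstat.geom,
    jsonlite,
    optparse,
    readr
Config/testthat/edition: 3
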