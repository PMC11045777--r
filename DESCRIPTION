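Package: varifoldmap
Title: Cross-Modality Mapping of Tissue Atlases to Molecular Data with
    Image Varifolds and LDDMM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Represents 2D tissue-scale atlases and molecular-scale point
    measurements (spatial transcriptomics detections, typed cells, binned
    stain intensities) as image varifolds: weighted Dirac measures over
    position crossed with a finite feature space. Jointly estimates a
    geodesic diffeomorphism of coordinates (large deformation diffeomorphic
    metric mapping, LDDMM) and a latent per-region feature law carrying the
    atlas ontology into the feature space of the target, by minimizing a
    reproducing-kernel varifold norm. Includes mesh and particle varifold
    constructions, an alternating LDDMM/quadratic-program optimizer and a
    joint gradient-based optimizer, accuracy and variance statistics for
    cross-replicate comparison and empirical atlas construction, and a
    synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    png,
    igraph,
    mgcv,
    MASS,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
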