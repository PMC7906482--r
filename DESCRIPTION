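Package: plantreg4d
Title: Skeleton-Driven Spatio-Temporal Registration of Plant Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-rigid registration of time-series 3D point clouds of individual
    plants for phenotyping. Extracts semantic curve skeletons from each scan
    (stem/leaf classification with an SVM on fast point feature histograms,
    density-based organ clustering, and per-organ self-organizing-map chains),
    estimates node correspondences between skeletons of consecutive scans with a
    hidden Markov model solved by the Viterbi algorithm, fits one affine
    deformation per skeleton node by robust Gauss-Newton least squares, warps and
    temporally interpolates the full point clouds, and tracks organ-level traits
    (leaf length and area, stem length and diameter) over time. Includes a
    deterministic synthetic plant generator with ground-truth skeletons,
    correspondences and deformations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    igraph,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
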