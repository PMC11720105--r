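Package: nhpnet
Title: Geometric Deep Learning for Reproducing Natural Head Position from
    Skull Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for automatically reproducing the natural head position
    (NHP) of a skull surface extracted from computed tomography. A skull
    mesh is converted into a fixed-size point cloud, normalized to the unit
    sphere, and fed to a two-stage set-abstraction network (farthest point
    sampling, radius grouping, density-corrected point convolution, global
    max pooling) that regresses the nine elements of a rotation matrix;
    the raw output is projected onto SO(3) by singular value decomposition.
    Training uses the Wing loss and the Adam optimizer with a halving
    learning-rate schedule. The package also provides CT global
    thresholding and isosurface extraction, STL input/output, a synthetic
    skull-proxy cohort generator with known ground-truth orientations, the
    antithetic angle augmentation scheme, and roll/pitch/yaw MAE and
    geodesic rotation-error evaluation with paired comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    withr,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
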