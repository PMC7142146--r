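Package: spharmcell
Title: Static and Dynamic Spherical-Harmonic Classification of Migrating
    Cell Shapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Classifies three-dimensional cell-migration shape patterns
    with rotation-invariant spherical-harmonic (SPHARM) descriptors, both
    static (single time point) and dynamic (time and frequency domain).
    Includes a lattice Monte-Carlo cell-migration simulator as a built-in
    synthetic data source, surface extraction from voxel occupancies or
    triangle-mesh files (OBJ, VRML97), an exact equiangular-grid
    spherical-harmonic transform, and a linear support-vector-machine
    cross-validation harness with naive-classifier controls and
    Mann-Whitney significance tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
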