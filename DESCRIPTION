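Package: spiculo
Title: Spiculated Tumor Phantoms and Robustness Analysis of 3D Radiomic
    Shape Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates mathematically defined spiculated tumor surface
    phantoms from real spherical harmonics, emulates a CT acquisition and
    segmentation chain by rasterizing the surfaces into binary voxel masks
    at configurable anisotropic spacing, reconstructs surfaces with four
    meshing strategies (isosurface extraction, curvature-weighted
    smoothing, isotropic remeshing, and an alpha-complex concave
    boundary), computes nine 3D radiomic shape features (volume, surface
    area, surface-to-volume ratio, three compactness formulas, spherical
    disproportion, sphericity, and fractional concavity) with
    mesh-consistent surface and volume, and runs robustness experiments
    quantifying how those features respond to spiculatedness, slice
    thickness, grid resampling, meshing algorithm, and tumor volume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
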