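Package: surfdose
Title: Surface-Scan-Based 3D Dose Calculation for Intraoperative
    Electron Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for computing three-dimensional electron-beam dose
    distributions on scanned surfaces of intraoperative electron radiation
    therapy (IOERT) surgical fields. A scanned surface (point cloud or
    triangle mesh) is reconstructed, registered to a reference CT through
    fiducial markers, closed into a watertight solid, voxelized into a
    two-valued air/water pseudo-CT, and used for dose calculation with a
    deterministic broad-beam electron model. Dose distributions are compared
    with a 3D gamma index (dose difference and distance to agreement, global
    normalisation, dose thresholds, tissue masking). A seeded synthetic
    phantom generator emulates an irregular surgical field with deep holes,
    fluid fill, fiducial markers, and single-viewpoint scanner acquisitions
    with occlusion and range noise.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
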