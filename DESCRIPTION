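Package: autorad3d
Title: 3D Reconstruction and Voxel-Wise Statistics for Autoradiographic
    Brain Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing chain for quantitative 2-deoxyglucose
    autoradiography of serially sectioned mouse brain: cleaning of
    digitized film sections (Otsu thresholding, morphological opening,
    largest-connected-component selection), gray-level to radioactivity
    calibration against co-exposed 14C standards by natural cubic spline,
    intra-subject 3D reconstruction by center-out sequential rigid
    alignment with a normalized cross-correlation metric, inter-subject
    spatial normalization by multi-resolution affine and B-spline
    registration to a smoothed reference template, and voxel-wise
    two-sample statistics with FWE and FDR control and cluster-size
    filtering. Includes a synthetic phantom generator with known ground
    truth so every stage is testable without film data.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
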