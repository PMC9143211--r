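Package: resectRT
Title: Dose-Volume Analysis of Segmental Mandibular Resections after Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses radiotherapy dose distributions with CT-derived bone models to
    quantify irradiated mandibular bone before and after virtual segmental
    resection. Reads DICOM CT series, RTDOSE grids and RTSTRUCT contour sets
    into one patient-space frame, reconstructs isodose volumes (e.g. the 56 Gy
    region), rasterises structures to voxel masks, extracts watertight surface
    meshes, applies osteotomy planes to partition the mandible into resected and
    residual segments, classifies each cut by lingual/buccal cortical
    involvement relative to the high-dose volume, and compares recurrent versus
    non-recurrent patient groups with normality-gated two-sample tests. Includes
    a synthetic phantom and cohort generator with fine-grid ground truth so the
    entire pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nortest,
    optparse,
    withr
Config/testthat/edition: 3
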