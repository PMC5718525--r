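Package: plugdose
Title: Gel and Film Dosimetric Verification of Plug-Based Gamma Knife Plans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end verification pipeline for stereotactic radiosurgery
    plans that use collimator plugging: a synthetic phantom generator
    (multi-shot dose grids with azimuthal plug shielding, virtual polymer-gel
    multi-echo MR measurements and virtual radiochromic film scans),
    voxelwise R2 mapping from CPMG echo series, linear R2-dose and
    per-channel quartic optical-density-dose calibrations, trilinear grid
    resampling in the stereotactic frame, and measured-versus-calculated
    comparison statistics (3D/2D gamma index with pass-rate tables, DVH,
    differential-DVH differences, dose-dependent dose-difference diagrams,
    line profiles and isodose contours). Dose grids round-trip through
    DICOM RT Dose and a lossless array-plus-JSON sidecar format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
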