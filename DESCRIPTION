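Package: scoutrange
Title: Automated Chest-CT Scan-Range Delimitation from Scout Views
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for automatic craniocaudal scan-range delimitation in
    chest CT from scout (localizer) views. Synthesizes scout-like 2D
    projections from 3D CT volumes, segments the lungs on those projections
    with either a residual dilated convolutional network or a deterministic
    classical segmenter, converts 2D lung masks into scan ranges with a
    one-voxel safety margin, quantifies signed overscanning against the
    3D ground truth, and accounts for the dosimetric impact of range
    selection (SSDE, DLP, a simplified organ-dose surrogate and ICRP-103
    effective dose) under exact, human-selected and predicted scenarios.
    Ships a synthetic anthropomorphic chest-phantom generator with tube
    current modulation so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
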