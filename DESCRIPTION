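Package: treereg
Title: Marker-Free Registration of Low-Overlap Terrestrial Laser Scans of
    Individual Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rigid registration of two terrestrial laser scans of a single
    dormant tree captured from opposed (180 degree) stations, where classical
    overlap-based registration fails. Branch stubs in a fixed radial ring
    around the trunk are extracted by Euclidean clustering and RANSAC
    cylinder fitting, described by radius, branch-trunk angle and centroid
    height, and matched with a dynamically weighted discriminant. The matched
    pair yields a closed-form coarse alignment (yaw about the projected-axis
    intersection, translation from basal-trunk cylinder centres), refined by
    branch-only trimmed point-to-point ICP. Includes ground-plane RANSAC
    preprocessing, statistical outlier removal, voxel downsampling, full
    evaluation metrics (axis-angle rotation error, translation and pointwise
    errors, completeness, structural parameters) and a procedural tall-spindle
    tree simulator with two-station self-occlusion for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
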