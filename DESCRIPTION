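Package: petnorm
Title: Anatomical Standardization and Z-Score Analysis of Torso FDG-PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for statistical analysis of standardized uptake value
    (SUV) volumes from torso FDG-PET scans. Deforms each subject onto a
    standard body using rule-based detection of eight bounding planes
    (neck-shoulder, arms-chest, thigh-hips, anterior/posterior, bladder and
    liver planes), piecewise affine registration of the resulting landmark
    cuboid, and thin-plate-spline registration of the body surface.
    Voxel-wise mean and standard-deviation grids accumulated over
    standardized normal scans form a sex-specific normal model, against
    which patient scans are converted into voxel-wise Z-score maps and
    region-level spot scores. Includes a synthetic torso phantom generator
    with complete ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    EBImage,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
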