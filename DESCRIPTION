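Package: vvhmotion
Title: Vector Volume Histogram Analysis of Respiratory-Induced Organ Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies respiratory-induced motion of a contoured structure
    from deformable image registration. Computes dense displacement vector
    fields between two CT volumes with an intensity-based cubic B-spline
    free-form-deformation registration, converts the field restricted to a
    structure mask into per-direction (left-right, anterior-posterior,
    cranio-caudal, 3D vector) length distributions, and summarises them as
    descending cumulative vector volume histograms with L_x% motion indices
    (L_min, L_95%, L_50%, L_5%, L_max), a centroid-displacement baseline, and
    a motion-management flag. Includes a digital moving-thorax phantom
    generator with analytic ground truth for validation, NIfTI-1 input and
    output, CSV/JSON reporting, and a command-line front-end.
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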