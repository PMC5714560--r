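Package: contourcast
Title: Contour Propagation and Ray-Cast Evaluation for Adaptive Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates serial pelvic CT phantoms with known deformations and
    multi-observer prostate contours, propagates planning contours through
    hierarchical affine and B-spline elastic intensity-based registration
    (normalized cross-correlation similarity, region-of-interest restriction),
    and evaluates propagation accuracy against inter- and intraobserver
    contouring variability using a 2048-ray radial surface sampling metric
    with per-ray two-tailed Student's t-tests. Includes NIfTI and DICOM
    RT-STRUCT contour input/output and a JSON contour interchange format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
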