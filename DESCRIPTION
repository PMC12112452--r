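Package: sacrozone
Title: CT-Based Safe-Zone Delineation for Sacroiliac Screw Placement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delineates a patient-specific safe zone for percutaneous
    sacroiliac screw placement from a CT volume. The pipeline segments the
    sacrum (by Hounsfield-unit thresholding with morphological cleanup, or
    from imported masks or freehand polygon tracings), resamples the
    anisotropic volume to isotropic spacing, computes full-field and masked
    lateral summation projections (virtual radiographs in HU*mm), extracts
    iso-density contours by marching squares, and delineates the
    high-density region of the first sacral vertebra as the screw-target
    safe zone with area, centroid and overlap metrics. A synthetic pelvic
    CT phantom generator with known ground truth supports end-to-end
    validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite,
    png,
    tiff
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
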