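Package: habseg
Title: Landmark-Guided Habenula Segmentation and Volumetry for High-Resolution MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating, delineating and measuring the human habenula on
    high-resolution T1-weighted structural MRI. Implements AC-PC rigid
    reorientation from manually placed commissure landmarks, a geometric
    per-slice delineation protocol for the posterior habenula with
    intensity-assisted region growing for anterior slices, ROI volumetry and
    centre-of-mass measurement, two-way random-effects intraclass correlation
    (ICC(2,1)) for inter-rater reliability, quantification of Gaussian-smoothing
    signal contamination from neighbouring structures, and a synthetic
    epithalamic phantom generator with ground-truth masks and landmarks so the
    full pipeline can be exercised and validated without real scans.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    EBImage,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
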