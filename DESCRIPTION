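Package: gkdosegel
Title: Polymer-Gel and Radiochromic-Film Dosimetry QA for Gamma Knife Single Shots
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: End-to-end quality-assurance analysis for Leksell Gamma Knife
    single-shot irradiations read out with normoxic polyacrylamide (nPAG)
    gel dosimeters and radiochromic films. Provides a synthetic phantom
    generator (analytic single-shot dose fields, dual-echo spin-echo MRI
    forward model with Rician noise, film scan forward model), two-point
    R2 (= 1/T2) mapping from dual-echo magnitude images, dose-response
    calibration with linear-range detection and inversion, planar dose-map
    reconstruction, FWHM profile comparison against treatment-planning
    reference widths, Sobel-based isodose segmentation with per-isodose
    structural similarity (SSIM) scoring, and a reproducible QA pipeline
    with machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    png,
    RNifti,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
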