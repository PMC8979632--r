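Package: sononav
Title: Ultrasound-Only Planning and Navigation for Non-Anatomical Liver Resection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Intra-operative planning and navigation computations for
    non-anatomical (atypical) liver resections driven solely by tracked
    freehand B-mode ultrasound. Provides rigid-transform and pixel-to-world
    geometry for calibrated tracked frames, an SVM contact classifier over
    near-field intensity statistics, streaming surface acquisition with local
    outlier factor (LOF) rejection and Hoppe-style tangent-plane mesh
    reconstruction, seeded graph-cut tumor segmentation with click
    refinement, conical resection-shape fitting around a spherical safety
    margin with resection-line extraction and US-plane overlay projection,
    and 3D tumor-to-specimen resection-margin measurement with R0/R1
    classification. A synthetic phantom module generates liver-like
    heightfield surfaces, embedded hyperechoic tumor mimics, speckled B-mode
    frames and tracked probe sweeps with full ground truth, so the whole
    pipeline is testable in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    igraph,
    EBImage,
    png,
    yaml,
    jsonlite,
    tibble,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
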