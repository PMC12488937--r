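Package: organoidqc
Title: Morphometric Quality Determination for Brain Organoids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quality assessment of early-stage brain organoids from 2-D
    brightfield morphometry. Segments organoid images and measures nine
    shape and cyst parameters in physical units, screens them against an
    expert High/Low quality rating by point-biserial correlation with
    false-discovery-rate control, clusters organoids with k-means and an
    elbow rule, derives a Youden-optimal single-parameter cutpoint
    (maximal Feret diameter), and links quality to mesenchymal-cell
    abundance estimated from bulk expression by constrained least-squares
    deconvolution. Includes a synthetic-cohort generator with known
    ground truth (rendered images, feature tables, expression mixtures,
    fluorescence panels) for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    pracma,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
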