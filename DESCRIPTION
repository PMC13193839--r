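Package: lungct
Title: Lung-Field Segmentation and Hybrid CNN-BiGRU Classification of Chest CT Slices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end pipeline for three-class (benign, malignant, normal)
    classification of 2-D axial chest CT slices. Preprocessing isolates the lung
    fields with CLAHE contrast enhancement, fixed-threshold binarisation,
    disk-based morphological refinement and edge-guided hole filling, then
    restricts the input to nodule-candidate pixels by intensity thresholding.
    Classification couples a convolutional backbone (global-average-pooled,
    projected to a 1024-wide descriptor) with a stacked bidirectional GRU head
    acting as a feature-gating mechanism, trained with Adam, mild geometric
    augmentation and early stopping. A seeded lung phantom generator with
    ground-truth masks supports fully synthetic, reproducible evaluation, and a
    confusion-matrix report module provides one-vs-rest precision, recall, F1
    and class-wise accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jpeg,
    yaml,
    jsonlite,
    withr,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
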