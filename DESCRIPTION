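Package: marrowquant
Title: Compartment Segmentation and Histomorphometry of H&E Bone-Marrow Sections
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Segments RGB brightfield H&E-stained bone sections into bone,
    hematopoietic, adipocytic and interstitium/microvasculature compartments
    (plus an undetected remainder), fragments delipidated adipocyte ghosts by
    membrane-guided watershed, and computes cellularity and adiposity
    statistics used in bone-marrow histomorphometry. Includes a stand-alone
    extramedullary adipocyte quantifier, QuPath-compatible GeoJSON annotation
    handling, a synthetic H&E section renderer with pixel-level ground truth
    for validation, and single-image and batch entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
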