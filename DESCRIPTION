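Package: reaver
Title: Segmentation and Quantification of Fluorescent Blood-Vessel Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Automated analysis of 2D fluorescence microscopy images of
    microvascular networks. Implements the REAVER (Rapid Editable Analysis of
    Vessel Elements Routine) two-stage pipeline: intensity-over-local-background
    segmentation built from averaging filters and binary morphology, followed by
    homotopic thinning to a unit-width centerline with Euclidean-distance-transform
    radius sampling and thickness-based segment pruning. Computes four
    vessel-architecture metrics (vessel length density, vessel area fraction,
    mean vessel diameter, branchpoint count), pixel-level confusion-matrix
    evaluation against ground-truth masks, and error/precision statistics.
    Includes a synthetic vascular-phantom generator with analytic ground truth
    for end-to-end validation, plus a batch command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
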