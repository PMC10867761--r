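Package: vesseltort
Title: Quantification of Retinal Vascular Tortuosity from Flat-Mount
    Vessel Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Semi-automated quantification of retinal vascular tortuosity
    from binary vessel-segmentation masks of murine flat-mounts, as used in
    oxygen-induced retinopathy (OIR) studies.  Masks are reduced to a
    unit-width skeleton, decomposed into a graph of vessel segments rooted
    at the optic disc, and scored with per-segment and per-image tortuosity
    metrics: the cumulative tortuosity index (CTI, arc-to-chord ratio),
    integrated curvature (IC, total absolute turning) and overall curvature
    (OC, mean turning angle).  Also included: Dice inter-grader agreement,
    neovascularization and vaso-obliteration area ratios with expert
    override, group statistics with significance stars, and a synthetic
    flat-mount generator with quadrature ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    tiff,
    jsonlite,
    yaml,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
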