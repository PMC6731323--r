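Package: ihcseg
Title: Patch-Based Tumour Segmentation and Ki67 Hotspot Detection for
    Immunohistochemistry Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for segmenting tumour from non-tumour tissue in
    Ki67/ER/PR immunohistochemistry (IHC) whole-slide images using a
    compact four-layer convolutional neural network trained on 64x64
    pixel patches, and for locating proliferation hotspots within the
    predicted tumour mask.  Includes a synthetic pseudo-slide generator
    with exact ground truth (polygons, label masks and DAB-positive
    nucleus masks), ImageScope-style XML annotation input/output and
    polygon rasterisation, mean-intensity tissue detection, sliding
    window patch extraction with dihedral augmentation, overlapping-tile
    whole-slide inference with pseudo-colour probability maps and
    lymphocytic-infiltrate exclusion, H-DAB colour-deconvolution based
    Ki67 hotspot scoring with subtractive clustering, and Dice/PPV/NPV
    style validation metrics against ground-truth annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
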