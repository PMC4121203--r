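Package: curvseg
Title: Curvelet-Based Segmentation and Quantification of Electron Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated offline analysis of scanning electron microscope (SEM)
    micrographs. Images are edge-enhanced by adding back the finest-scale band
    of a tight-frame discrete curvelet transform, segmented by local
    Shannon-entropy texture filtering followed by thresholding and
    mathematical-morphology refinement, and quantified by box counting:
    per-region area, boundary-box perimeter and fractal dimension. A
    gradient-flooding watershed baseline and a deterministic synthetic
    SEM-scene generator with exact ground truth support validation and
    method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
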