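Package: fibergrade
Title: Collagen Fiber Density and Alignment Analysis for SHG Tissue Microarray Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantifying fibrillar collagen in second harmonic
    generation (SHG) images of tissue-microarray cores and comparing tumor
    grades. Includes a synthetic image generator with known ground-truth fiber
    populations, H&E-to-SHG image registration by color segmentation and
    iterative intensity matching, a FIRE-style fiber extractor based on
    distance-transform ridge tracing, per-ROI density and circular-statistics
    alignment metrics, and a random-intercept linear mixed-effects comparison
    of grade groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    nlme,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
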