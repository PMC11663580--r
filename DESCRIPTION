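Package: hullgrow
Title: Colour-Hull Image Segmentation and Growth Rate Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments plant and macroalgal photographs by specifying the
    target colour volume as a convex or alpha hull in CIELAB colour space
    and classifying pixels by containment in, or Euclidean colour distance
    (Delta E) to, the hull surface. Detects circular fiducial markers to
    assign indexed regions of interest across a multiplexed image series,
    aggregates per-unit foreground areas over time, and estimates relative
    growth rates as the slope of a log-linear fit with model-fit quality
    flags. Includes a synthetic-fixture generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, grDevices, utils, tools, EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, Visualization, Segmentation, CellBasedAssays
RoxygenNote: 7.3.3
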