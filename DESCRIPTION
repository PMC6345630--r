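Package: rodsizer
Title: Geometry-Based Cell-Size-Control Analysis for Rod-Shaped Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyze how rod-shaped cells such as fission yeast
    sense their size at division. Implements spherocylinder cell-geometry
    quantification from segmented contours (surface area and volume by
    profile rotation, single-cell closed forms, and population mean
    radius), cortical node fluorescence quantification (axial intensity
    projection, Gaussian peak fitting, nodal intensity and density), a
    steady-state flux-balance model of Cdr2 nodal scaling, and the
    model-discrimination statistics used to distinguish length, area and
    volume sensing: binned homeostasis regressions, normalized RMSD with
    Monte Carlo p values, generalized size-measure exponent scans, and
    log-log division-geometry fits with chi-squared tests. A synthetic
    rod-cell generator (lineages, contours, fluorescence images) makes
    every stage testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    tiff
Config/testthat/edition: 3
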