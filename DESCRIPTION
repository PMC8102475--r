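Package: flerq
Title: Quantification of Dynamic Indocyanine Green Fluorescence Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of dynamic indocyanine green (ICG)
    fluorescence angiography recordings. Computes per-pixel 25-75% rise-time
    (time-to-peak, TTP) perfusion maps from timestamped grayscale image stacks,
    renders fluorescence-based enhanced reality (FLER) perfusion cartography
    overlays, extracts per-ROI mean TTP and absolute-intensity extrema, and
    summarizes repeated-assessment protocols: censored local capillary lactate
    means, per-assessment hemodynamics, and paired small-sample contrasts of
    perfusion metrics across vasopressor doses. A synthetic videography module
    simulates pixel-wise ICG bolus wash-in kinetics with dye accumulation
    across repeated injections, so the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
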