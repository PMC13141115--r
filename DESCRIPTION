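Package: mifprep
Title: Preprocessing and Imaging Cytometry for Sequential Multiplex
    Immunofluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Image preparation pipeline for sequential (cyclic) multiplex
    immunofluorescence microscopy: flat-field shading correction by
    reference division, phase-correlation tile stitching with feathered
    blending, rolling-ball background subtraction, brightfield flattening
    by Gaussian division, weighted-average z-projection, DAPI-referenced
    cross-cycle registration with tissue-retention quality control,
    multichannel hyperstack assembly, autofluorescence subtraction, and
    downstream imaging cytometry (nucleus segmentation, per-cell marker
    overlap fractions, and identity assignment by a nuclear-overlap rule).
    Includes a seeded synthetic-acquisition generator with ground truth so
    every stage is testable without real data, and a command-line entry
    point for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
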