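Package: aggflux
Title: Exchange Kinetics and Quantitative Time-Lapse Imaging of Neuronal
    Protein Aggregates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the sequestration of aggregation-prone
    cytosolic proteins (such as polyglutamine-expanded huntingtin exon-1
    fragments) into micron-scale inclusions in cultured neurons. Provides
    an explicit cytosol-aggregate exchange kinetic model with pulse-chase
    label bookkeeping, a synthetic multi-channel z-stack time-lapse
    generator with ground truth, punctum detection and tracking on
    maximal-intensity projections, ROI and cytosolic intensity traces,
    neurite-compartment assignment, FRAP recovery fitting, pulse-chase
    turnover summaries, and an orchestration layer with OME-TIFF and CSV
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    tiff,
    xml2,
    yaml,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
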