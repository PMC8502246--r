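Package: uavstand
Title: Plant and Head Counting from Multispectral UAV Captures
Version: 0.1.0
Authors@R:
    person("Field", "Phenomics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A high-throughput phenotyping pipeline that turns raw
    multispectral UAV captures into per-plot nadir reflectance images and
    counts sorghum plants and heads. Covers radiometric calibration of raw
    digital numbers to reflectance via a calibrated reference panel,
    band-to-band registration with an enhanced-correlation-coefficient
    optimiser, reverse projection of world plot and row boundaries through a
    digital surface model into individual captures, nadir capture selection,
    OSAVI/OTSU plant stand counting, and two-step GEMI/red-edge head
    segmentation with circularity-based declustering of overlapping heads
    using kernel-density threshold selection. Includes a synthetic flight
    generator with known ground truth so the whole pipeline is testable
    end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
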