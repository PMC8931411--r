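Package: croptransfer
Title: Cross-Year Training-Sample Transfer for Satellite Crop Mapping
Version: 0.1.0
Authors@R:
    person("Croptransfer", "Developers", email = "croptransfer@example.org",
           role = c("aut", "cre"))
Description: Generates training samples for a target year from labeled crop
    samples of a historical year by measuring dynamic-time-warping similarity
    between fitted spectral-phenology curves ("feature curves") of each
    historical sample and the pixels of its target-year neighborhood. Potential
    samples are screened per crop by k-means clustering with silhouette-based
    model selection, and the surviving samples train a bagged decision-tree
    ensemble for crop-type mapping, evaluated with standard confusion-matrix
    accuracy metrics. Includes a synthetic multi-year scene simulator with
    crop-specific NDVI phenology, inter-annual phase shifts, cloud gaps and
    configurable crop rotation, so the whole pipeline is testable end to end
    without external imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
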