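Package: fieldmapr
Title: Cropland Field-Boundary Mapping from Daily 4-Band Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale implementation of a national cropland field-boundary
    mapping workflow for smallholder-dominated landscapes. Converts daily
    4-band (blue, green, red, near-infrared) surface-reflectance stacks into
    haze- and shadow-robust weighted seasonal composites, scores crowdsourced
    polygon annotations and fuses them into quality-weighted consensus labels
    with a Bayes-risk disagreement measure, trains a balanced random-forest
    cropland classifier inside an uncertainty-driven active-learning loop,
    delineates individual crop fields with a compact-watershed plus
    region-adjacency-graph segmentation of the dry-season composite, and
    performs stratified map-accuracy assessment with unbiased area estimation
    and field-size bias correction. Includes a seeded synthetic-landscape
    simulator (fields, clouds, shadows, labellers of controllable skill) so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    Rcpp,
    ranger,
    mgcv,
    geosphere,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
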