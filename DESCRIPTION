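Package: rangeprofile
Title: Species Range Metrics, Ensemble Distribution Models and
    Conservation Profiles from Occurrence Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the geographic range metrics used in IUCN Red List
    criterion B assessments - extent of occurrence (minimum convex
    polygon) and area of occupancy (2 x 2 km occupancy grid) - from
    georeferenced occurrence records, either directly from the points
    (observed basis) or from an uncertainty-propagating ensemble of
    presence-background suitability models with AUC-weighted consensus
    and confidence-limit maps, followed by restriction of predictions to
    habitat patches that contain observations.  Applies data-deficiency
    and criterion-B range-threshold rules, ships an encoded set of 43
    published species conservation profiles of spiders endemic to
    mainland Portugal, and reproduces their aggregate tallies.  Includes
    a seeded virtual-species simulator (smoothed random environmental
    layers, suitability-weighted presence sampling, positional error) so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    glmnet,
    igraph,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
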