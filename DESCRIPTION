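Package: floorplate
Title: Multi-Animal Home-Cage RFID Floor-Plate Tracking Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing and analysis of raw RFID floor-plate detection logs
    from group-housed rodents: per-second multi-animal trajectory
    reconstruction (first-detection-wins downsampling and forward fill),
    locomotor-activity metrics over light/dark and arbitrary windows,
    four-ring spatial proximity classification, the Close Contact Ratio
    (CCR) sociability statistic, Cytoscape-ready social-network edge
    tables, and group-level behavioral phenotyping (feature extraction,
    PCA, k-means with silhouette-based cluster selection, coefficient of
    variation, chi-square and Holm-Sidak statistics). Includes a seeded
    home-cage simulator with circadian movement, social attraction and
    sensor noise so every pipeline stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    Rcpp,
    lubridate,
    cluster,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
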