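Package: pgxvar
Title: Comparative Characterization of Pharmacogenomic, Disease and
    Neutral Missense Variants
Version: 0.1.0
Authors@R: person("pgxvar", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Feature extraction, class-weighted random-forest
    discrimination and trend statistics for comparing pharmacogenomic
    (PGx), disease-associated and neutral missense variants. Computes
    structure-derived features (side-chain-centroid neighbourhoods,
    neighbour conservation, DSSP accessibility and secondary structure),
    sequence-derived features (normalized evolutionary rates,
    physicochemical substitution deltas), balanced classification
    metrics, Kendall tau-b trend tests and Wilcoxon rank-sum tests, and
    ships a calibrated synthetic-data generator so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
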