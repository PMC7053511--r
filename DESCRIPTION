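Package: herdnet
Title: Activity-Stratified Proximity Networks for Grazing Herds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and analyses binary proximity networks from focal-sampling
    observations of a grazing herd. Observation records (one activity and a set
    of proximity partners per animal per 30-minute period) are turned into an
    ensemble of simple undirected networks, one per activity and period, over
    the fixed full-herd vertex set. Global indices (density, number of
    components, clustering coefficient) and vertex centralities (degree,
    closeness, betweenness, eigenvector) are computed from first principles,
    and Spearman rank correlations associate activities and animal attributes
    (age, gender) with these indices. A seeded synthetic-herd generator
    emulates the observation design so the whole pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
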