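Package: foragesim
Title: Individual-Based Simulation of Collective Refuge-to-Forage Movement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic individual-based model of a small animal group moving
    along a one-dimensional corridor from a safe refuge to a foraging site.
    Individuals differ consistently in boldness (the rate at which their
    outward-movement probability grows) and optionally follow one of three
    social interaction rules (move towards the group centroid, towards the
    nearest neighbour, or with the local majority). The package provides a
    fast compiled engine and a readable pure-R reference engine, event-time
    observers (departure, arrival, travel, latency), deterministic seeded
    parameter-sweep protocols, and the analysis layer used to quantify how
    social behaviour erodes inter-individual (personality) variation:
    within-group min-max rescaling, one-way and repeated-measures ANOVA
    variance partitioning, and a paired social-minus-non-social ordering
    difference metric.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
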