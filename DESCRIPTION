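Package: pmdnet
Title: Seeded Protein-Metabolite-Drug Interaction Networks with
    Confidence Scoring and Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a local, deduplicated store of protein, metabolite,
    gene and drug interaction evidence from tab-separated interaction
    tables (a native dialect and a PSI-MI TAB 2.5 column subset),
    expands seed lists into attribute-rich subnetworks, and attaches
    three confidence measures to the result: an additive evidence Class
    score mapped to classes A-E and rendering widths, the Functional
    Similarity Weight (FSWeight) topological edge-reliability score, and
    a binomial-proportion node significance p-value.  Performs
    hypergeometric enrichment of Gene Ontology biological-process and
    KEGG pathway term sets with an overflow-safe handoff from direct
    factorial evaluation to log-gamma summation, computes degree and
    FSW-distribution topology diagnostics with power-law slope fitting,
    and serializes networks to Cytoscape-compatible XGMML.  A seeded
    synthetic-fixture generator emulates the statistical structure of
    the integrated interaction databases so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
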