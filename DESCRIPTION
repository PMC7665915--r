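Package: chmnet
Title: Co-Prescription Network Analysis for Chinese Herbal Medicine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing herbal co-prescription patterns in
    claims-style prescription data: cohort description with grouped
    counts and chi-square tests, association-rule mining of herb pairs
    (support, confidence, lift), construction and modularity-based
    clustering of the co-prescription network, identification of core
    herbs by prevalence and degree centrality, ingredient screening by
    oral bioavailability and drug-likeness, target-protein aggregation
    per network cluster, and hypergeometric overrepresentation analysis
    of cluster target sets against a pathway collection with FDR
    control. A synthetic-data module generates cohort tables,
    transactions with planted co-prescription communities, ingredient
    and target tables, and pathway collections so that the whole
    pipeline runs and is testable without access to the original
    claims database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    mclust,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
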