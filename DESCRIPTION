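Package: netprio
Title: Benchmarking Protein Interactome Networks for Cancer Gene Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks genes in protein-protein interaction networks by topological
    centrality (degree, betweenness) and benchmarks how well each network
    recovers a gold-standard cancer gene set. Provides threshold-sweep
    classification metrics (recall, accuracy, specificity), permutation-null
    fold enrichment with empirical p-values, random edge-removal robustness
    profiling, cross-network relative-rank and top-k overlap comparison, and
    somatic mutation-frequency analysis from MAF tables with rank-sum
    comparison of top- versus bottom-ranked genes. Includes a seeded
    synthetic-data generator (scale-free networks, hub-biased positive gene
    sets, planted mutation tables) so the whole pipeline is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
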