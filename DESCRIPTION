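Package: wncnet
Title: Weighted Node Connectivity Hub Detection in Gene Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate hub genes in gene co-expression networks with
    the weighted node connectivity (WNC) score, a weighted generalization of node
    degree, together with a permutation-based statistical test. Networks are built
    from expression matrices as complete graphs weighted by absolute Pearson
    correlation; per-gene empirical P-values are estimated against a null obtained
    by randomly reassigning edge weights (weight-swap or full-shuffle), preserving
    the network's topology, degree sequence and weight distribution, and adjusted
    with a Bonferroni correction. Alternative weight aggregations (mean, sum of
    squares), the four classical binary-network centrality measures (degree,
    closeness, betweenness, clustering coefficient) with percentile-based top-gene
    selection, Fisher-exact gene-set enrichment, seeded synthetic data generators
    with planted hub modules, and a command-line interface are included.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    Matrix,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
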