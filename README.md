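# wncnet

Hub-gene detection in gene co-expression networks with the **weighted node
connectivity (WNC)** score and a permutation-based statistical test.

## The problem

In a gene co-expression network, nodes are genes and edges carry the strength
of their expression association — here the absolute Pearson correlation
|ρ<sub>ij</sub>| between expression profiles, so strong negative co-expression
counts the same as strong positive co-expression. Highly connected genes
("hubs") in such networks are candidate regulators and disease genes. The
classical route to finding them — thresholding the correlations into a binary
graph and computing degree, closeness, betweenness or clustering coefficient —
discards the weight information, depends on an arbitrary cut-off, and offers
no per-gene indicator of statistical significance.

`wncnet` implements the weighted alternative. For gene *i* in a network with
weights w<sub>ij</sub>:

- **WNC<sub>i</sub> = Σ<sub>j</sub> w<sub>ij</sub>** — the sum of all incident
  edge weights (a weighted degree);
- **WNCB<sub>i</sub> = Σ<sub>j</sub> w<sub>ij</sub> / N<sub>i</sub>** — the
  mean incident weight (N<sub>i</sub> = neighbor count);
- **WNCC<sub>i</sub> = Σ<sub>j</sub> w<sub>ij</sub>²** — the sum of squared
  weights, emphasizing strong edges.

Each observed WNC<sub>i</sub> is compared against an empirical null obtained by
randomly reassigning the observed weight multiset to the edges — either by a
chain of weight swaps between node-disjoint edge pairs (`mode = "swap"`) or by
a full random shuffle of the weights (`mode = "shuffle"`, the default). Both
preserve the network's node set, topology, degree sequence and weight
distribution exactly. The nominal P-value for gene *i* is the proportion of
permuted samples whose null score is ≥ the observed score; P-values are
Bonferroni-adjusted over the genes tested, and genes with adjusted P < 0.05 are
flagged as candidate hubs.

For comparison the package also implements the four classical binary-network
centralities (degree, closeness, betweenness, clustering coefficient) on the
percentile-thresholded network, top-percentile gene selection, gene-set overlap
reports, Fisher-exact (hypergeometric) gene-set enrichment against GMT
annotations, and seeded synthetic expression generators with planted hub
modules for validation.

## Worked example

Simulate 60 genes over 40 samples with one planted module of 8 genes driven by
a shared latent factor (gene–driver correlation 0.95), build the network, and
test:

```r
library(wncnet)

spec <- hub_spec(n_genes = 60, n_samples = 40, n_hubs = 1, module_size = 8,
                 driver_strength = 0.95, seed = 42)
sim <- generate_expression(spec)
net <- compute_correlation_network(sim$expr)    # complete graph, 1770 edges
res <- run_wnc(net, permutation_config(n_permutations = 10000, seed = 1))
head(res, 10)
```

```
   gene_id   wnc  wncb wncc p_nominal p_adjusted rank significant
1     g001 12.23 0.207 6.52    0.0000      0.000    1           1
2     g002 12.59 0.213 6.51    0.0001      0.006    2           1
3     g005 12.55 0.213 6.33    0.0001      0.006    3           1
4     g003 12.48 0.211 6.74    0.0001      0.006    4           1
5     g004 12.47 0.211 6.72    0.0002      0.012    5           1
6     g007 12.46 0.211 6.46    0.0002      0.012    6           1
7     g006 12.01 0.204 6.09    0.0004      0.024    7           1
8     g008 12.07 0.205 6.54    0.0005      0.030    8           1
9     g056 10.15 0.172 2.79    0.0390      1.000    9           0
10    g044  9.34 0.158 2.20    0.1385      1.000   10           0
```

All 8 planted module genes (g001–g008) — and nothing else — are significant at
adjusted P < 0.05; the top gene's observed WNC beat all 10,000 null samples
(P = 0). Note the ranking is by P-value, not by raw WNC: g001 ranks first with
a slightly lower WNC than g002 because significance, not raw connectivity, is
the selection criterion.

Comparing with the classical route on the thresholded binary network:

```r
b <- threshold_network(net, 0.95)               # 52 nodes, 89 edges
tab <- centrality_table(b)
top_deg <- select_top_percentile(setNames(tab$degree, tab$gene_id), 0.95)
set_overlap(list(wnc = res$gene_id[res$significant == 1], degree = top_deg))$pairwise
```

```
  set_a  set_b overlap
1   wnc degree       3
```

The degree score finds 3 of the 8 module genes; WNC recovers the full module.

The same pipeline is available from the shell via the bundled CLI
(`system.file("cli", "wncnet", package = "wncnet")`), with subcommands
`simulate`, `build`, `wnc`, `centrality`, `enrich` and `compare`; every run
writes a `manifest.json` recording the seed, permutation count, input checksums
and package version.

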