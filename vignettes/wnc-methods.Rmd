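---
title: "Weighted node connectivity: model, null distribution and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted node connectivity: model, null distribution and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wncnet)
```

## The statistic and its test

A gene co-expression network is built here as a *complete* weighted graph: for
every pair of genes $i, j$ the edge weight is $w_{ij} = |\rho_{ij}|$, the
absolute Pearson correlation between their expression profiles. Taking the
absolute value treats strong negative co-expression as equally informative;
completeness means no correlation threshold has to be chosen for the weighted
analysis.

The hub score of gene $i$ is its weighted node connectivity,

$$\mathrm{WNC}_i = \sum_j w_{ij},$$

with two alternative aggregations on different scales: the mean incident
weight $\mathrm{WNCB}_i = \mathrm{WNC}_i / N_i$ ($N_i$ = neighbor count) and
the squared-emphasis sum $\mathrm{WNCC}_i = \sum_j w_{ij}^2$. On a complete
graph the divisor $N_i = N - 1$ is constant, so WNC and WNCB induce the same
ranking by construction; WNCC re-weights toward genes with a few very strong
edges over genes with many moderate ones.

A raw connectivity score cannot separate "many weak edges" from "several
strong ones", so each $\mathrm{WNC}_i$ is tested against an empirical null
distribution of $\mathrm{WNC}_{i,\mathrm{random}}$ values computed on
randomized networks. The randomization keeps the node set, the edge topology
(hence the degree sequence) and the multiset of weights exactly fixed and only
reassigns weights to edges, so the null answers precisely the question of
interest: *given this network's connections and this pool of co-expression
strengths, how surprising is the concentration of strength at gene $i$?*

The nominal P-value is the inclusive proportion

$$P_i = \frac{\#\{\mathrm{samples}: \mathrm{WNC}_{i,\mathrm{random}} \ge \mathrm{WNC}_i\}}{\#\mathrm{samples}},$$

Bonferroni-adjusted over the number of genes submitted for testing (the whole
node set by default, or a user-supplied gene list, in which case the
multiplicity is the list length). Genes with adjusted $P < \alpha$ (default
0.05) are flagged. Ranking is by ascending adjusted P, ties broken by
descending WNC and then gene id, so output files are deterministic.

Two estimator details are deliberate:

* **Ties count against significance.** The comparison is $\ge$, so a null
  sample exactly equal to the observed score increments the count. On an
  equal-weight network every permutation reproduces the observed scores and
  every $P_i = 1$ — the correct degenerate answer.
* **Plain proportion, no pseudocount.** $P = 0$ is attainable when the
  observed score beats every null sample, which is the natural report for an
  extreme hub at a finite permutation budget. A `pseudocount` option
  ($P = (b+1)/(m+1)$) is available for users who prefer a strictly positive,
  slightly conservative estimator.

## The two null-model modes

`mode = "swap"` follows the weight-swap procedure literally: repeatedly draw
two edges $e(x,y)$, $e(v,z)$ uniformly at random and, when all four endpoints
are distinct, exchange their weights. `mode = "shuffle"` assigns the weight
multiset to the edges in one uniformly random permutation. Both preserve the
same invariants; shuffle is the default because it is the stationary
distribution of the (ergodic) swap chain at a fraction of the cost, and
because it is well defined on every topology — swap mode has no valid move on
a star or triangle, where no node-disjoint edge pair exists, and raises an
explicit error suggesting shuffle.

Two conventions in swap mode deserve a note:

* **Chain length counts attempts, not accepted swaps** (default
  $10\,|E|$ attempts per sample; rejected draws are no-ops). Besides being
  the natural cost measure, this avoids a parity artifact on very small
  graphs: on the complete 4-node graph exactly three disjoint-pair
  transpositions exist, they commute, and the reachable set of assignments is
  a group of $2^3 = 8$ elements. A fixed count of *accepted* swaps would fix
  the parity of the generator counts and confine each sample to half of that
  set; a random accepted count (binomial over attempts) restores convergence
  to the uniform distribution on the reachable component. The test suite
  checks this by enumerating the reachable assignments and comparing visit
  frequencies by chi-square.
* **On small graphs the swap chain's support can be a strict subset of all
  weight assignments** (the 8-element group above, versus $6! = 720$
  assignments for shuffle). On large, dense networks the two nulls coincide
  for practical purposes; where they differ, shuffle is the better-defined
  reference and is what the exhaustive-enumeration oracle in the tests
  targets.

Reproducibility: every permuted sample is fully determined by
`(seed, sample_index)` through a per-sample derived seed, so sample $i$ of a
$10^5$-permutation run can be regenerated in isolation by
`permute_weights(net, config, i)`, and identical configurations yield
byte-identical result files.

## Network construction and thresholding

The classical centralities operate on a binary network obtained by keeping
the edges whose weight is at or above a percentile of the weight distribution
(default 0.95). The percentile is computed by the **nearest-rank** convention
— the order statistic at ascending rank $\lceil p \cdot E \rceil$ — with an
inclusive $\ge$ comparison, so all edges tied at the threshold are retained
and with continuous weights a fraction $\approx 1 - p$ of edges survives.
Nodes left without any retained edge are dropped. The same convention selects
"top percentile" genes from a centrality score vector, so with heavy ties the
selected set may exceed $(1-p)$ of the genes — with all scores equal, every
gene is returned.

Degenerate expression input is rejected rather than repaired: missing values
error at load (no silent imputation rule is applied), fewer than 3 samples
error (Pearson correlation is degenerate), and a constant expression profile
errors naming the gene (its correlation is undefined; scoring it 0 would
silently distort the hub ranking).

## Classical centralities

Degree, closeness, betweenness and clustering coefficient are implemented
from their definitions on the binary network:

* **Closeness** is $1/\sum_j h(i,j)$ with unweighted shortest-path distances,
  summed over the node's connected component. Nodes in small components can
  therefore report deceptively high closeness — a known caveat, reported
  as-is.
* **Betweenness** is the raw sum over unordered pairs $\{j,k\}$ of the
  fraction of shortest $j$–$k$ paths through $i$ (Brandes accumulation). An
  optional normalization by $\binom{n-1}{2}$ is provided; it is a monotone
  rescaling, so percentile-based selection is unaffected by the choice.
* **Clustering coefficient** of a degree-1 node is reported as 0 (the common
  tool convention) since its denominator $\binom{d}{2}$ vanishes.

The test suite validates all four against naive brute-force oracles
(exhaustive simple-path enumeration for betweenness, adjacency-power
distances for closeness, direct neighborhood counting for clustering) on
hundreds of random graphs of up to 7 nodes, and against an independent graph
library.

## Enrichment

Gene-set enrichment of a selected set is the one-sided Fisher exact
(hypergeometric upper-tail) test per term,
$P = \sum_{x \ge k} \binom{K}{x}\binom{N-K}{n-x} / \binom{N}{n}$, with
Bonferroni correction over the terms tested. Only over-representation is
tested. The universe defaults to the annotated genes and should be set to the
analyzed network's gene set when the selection came from a network — the
selection was drawn from that sampling frame, not from the genome. Annotations
are intersected with the universe at load; terms left empty are rejected.

## The synthetic generator

`generate_expression()` plants hub modules in background noise: each module
has a latent standard-normal driver over samples, and each module gene is
$a \cdot \mathrm{driver} + \sigma \varepsilon$ with
$a = \sigma s / \sqrt{1 - s^2}$, so its population correlation with the driver
is exactly $s$ (`driver_strength`), independent of the noise scale $\sigma$.
Two module genes share only the driver, so their population correlation is
$s^2$ — an invariant the tests check in closed form at large sample counts.
Background genes are i.i.d. noise. An option flips the loading sign for half
of each module, producing strong negative correlations that exercise the
absolute-value weighting. The generator emulates the *structure* the method
targets (groups of genes with prominent, coherent connectivity against an
uncorrelated background at small sample size, around ten samples and a few
hundred genes) and deliberately not the technical artifacts of real
expression data — library-size effects, normalization residuals,
heavy-tailed noise, correlated background blocks. Passing tests on it
demonstrate the statistical machinery, not robustness to those artifacts.

## Statistical power at small sample sizes — a known limitation

The reference fixture used across the tests plants 2 modules of 15 genes in
200 genes over **10 samples** at driver strength 0.9. At 10 samples the
background absolute correlations are large ($E|r| \approx 0.27$ under
independence), so a hub gene's excess connectivity — roughly
$14 \times (0.81 - 0.27) \approx 7.5$ over a null spread of $\approx 2.9$ —
corresponds to nominal P-values of a few percent. That separates hubs cleanly
in the *ranking* (the suite asserts a rank-sum AUC well above chance, and the
acceptance run reports a strong negative correlation between WNC and nominal
P), but it is two orders of magnitude short of the $2.5\times10^{-4}$ nominal
level that Bonferroni significance at $m = 200$ requires. Recovery of these
planted hubs *as adjusted-significant calls* at 10 samples is therefore
essentially nil — the corresponding end-to-end recovery check in the
acceptance suite documents this honestly rather than relaxing the fixture.
With more samples the background correlations shrink and the same module
becomes unambiguous: at 40 samples and driver strength 0.95 all planted genes
reach adjusted $P < 0.05$, the top gene at $P = 0$ (the README's worked
example computes exactly this). Practical guidance: with of order ten samples,
treat WNC P-values as a ranking device and expect Bonferroni-level calls only
for very strong modules; the permutation test gains power rapidly with sample
count because both the observed weights sharpen and the null pool tightens.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at sizes chosen to keep a
full check under a few minutes on one CPU while leaving Monte-Carlo error
negligible relative to the asserted tolerances: exhaustive enumeration on the
4-node/6-edge network (720 assignments) against $5\times10^4$ empirical
samples compared at 3 Monte-Carlo standard errors; 1,000 conservation checks
on a 50-node network; the $10^4$-vs-$10^5$ permutation stability comparison
on a 100-node network (agreement within 3 binomial standard errors for at
least 99% of genes); 200 brute-force centrality comparisons on graphs of at
most 7 nodes; and exhaustive hypergeometric enumeration for every universe
size up to 12. Permutation scoring is vectorized through a sparse
node-by-edge incidence matrix; observed scores are computed through the same
matrix product as null scores so both sides of the $\ge$ comparison share the
same floating-point summation order, and enumeration tests use dyadic weights
(all subset sums distinct and exactly representable) so no comparison can
flip on rounding. Network edge lists are written with 17 significant digits
and round-trip exactly; result tables are human-oriented (6 significant
digits, scientific notation below $10^{-4}$).

## Other deliberate scope decisions

* Only Bonferroni correction is built in: it is conservative, which suits
  exploratory hub screening where false positives are the pressing risk. The
  nominal P column is always present, so any other correction can be applied
  downstream; FDR control is an obvious hook point left to the caller.
* The null keeps topology fixed and moves weights; degree-preserving rewiring
  that changes topology answers a different question and is out of scope.
* Non-linear association measures (mutual information, distance correlation)
  and soft-thresholding/power-adjacency network construction are out of
  scope; the scoring machinery is agnostic to how the weights in $[0,1]$ were
  produced, so such networks can be supplied directly as edge lists.
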