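#' Permutation test configuration
#'
#' Settings for the weight-randomization null model. Two modes produce null
#' networks with identical node set, edge topology (hence degree sequence) and
#' weight multiset; only the assignment of weights to edges changes:
#'
#' * `"shuffle"` (default): a uniformly random assignment of the observed
#'   weight multiset to the edges. This is the stationary distribution of the
#'   swap chain (when that chain is ergodic) at a fraction of the cost, and is
#'   well defined on every topology.
#' * `"swap"`: a Markov chain of pairwise weight swaps. Each step draws two
#'   edges uniformly at random; if they share no node (`x != y != v != z`)
#'   their weights are exchanged, otherwise the step is a no-op. Counting
#'   attempted rather than accepted swaps keeps the number of applied
#'   transpositions random, which avoids parity artifacts on very small
#'   graphs where few disjoint pairs exist.
#'
#' @param n_permutations Number of permuted samples (default 100000, the
#'   published default; tests and exploratory runs typically use 1000-10000).
#' @param n_swaps Swap attempts per sample in `"swap"` mode, or `"auto"`
#'   (default) for `10 * n_edges`, well past mixing on complete graphs.
#' @param seed Integer seed fixing the entire null-sample stream; sample
#'   `i` is reproducible in isolation via [permute_weights()].
#' @param mode `"shuffle"` (default) or `"swap"`.
#' @param pseudocount If `TRUE`, estimate P as `(b + 1) / (m + 1)` instead of
#'   the plain proportion `b / m`. The plain proportion (default) can report
#'   P = 0 when the observed score exceeds every null sample, as the published
#'   method does; the add-one variant is never 0 and is slightly conservative.
#' @return An object of class `permutation_config`.
#' @export
permutation_config <- function(n_permutations = 100000L, n_swaps = "auto",
                               seed = 1L, mode = c("shuffle", "swap"),
                               pseudocount = FALSE) {
  mode <- match.arg(mode)
  n_permutations <- as.integer(n_permutations)
  if (is.na(n_permutations) || n_permutations < 1L) {
    stop("'n_permutations' must be a positive integer")
  }
  if (!identical(n_swaps, "auto")) {
    n_swaps <- as.integer(n_swaps)
    if (is.na(n_swaps) || n_swaps < 1L) {
      stop("'n_swaps' must be a positive integer or \"auto\"")
    }
  }
  structure(
    list(n_permutations = n_permutations, n_swaps = n_swaps,
         seed = as.integer(seed), mode = mode,
         pseudocount = isTRUE(pseudocount)),
    class = "permutation_config"
  )
}

#' Weighted node connectivity (WNC)
#'
#' The hub score: for each node, the sum of the weights of all incident
#' edges — a weighted generalization of node degree. Nodes with no edges
#' score 0.
#'
#' @param net A [weighted_network()].
#' @return Named numeric vector over `net$nodes`.
#' @export
wnc_scores <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  s <- numeric(length(net$nodes))
  acc <- rowsum(c(net$weight, net$weight), c(net$from, net$to))
  s[as.integer(rownames(acc))] <- acc[, 1L]
  names(s) <- net$nodes
  s
}

#' Mean incident edge weight (WNCB)
#'
#' WNC divided by the node's neighbor count: the mean of the observed incident
#' edge weights. On a complete graph of `N` nodes this is `wnc / (N - 1)`
#' exactly, so its ranking coincides with WNC's. Isolated nodes have no mean
#' and are an error.
#'
#' @param net A [weighted_network()].
#' @return Named numeric vector over `net$nodes`.
#' @export
wncb_scores <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  deg <- node_degrees(net)
  if (any(deg == 0L)) {
    stop("wncb is undefined for isolated node(s): ",
         paste(utils::head(net$nodes[deg == 0L], 5L), collapse = ", "))
  }
  wnc_scores(net) / deg
}

#' Sum of squared incident edge weights (WNCC)
#'
#' An aggregation that emphasizes strong connections: each incident weight
#' enters squared. With all weights equal to 1 it reduces to the degree.
#'
#' @param net A [weighted_network()].
#' @return Named numeric vector over `net$nodes`.
#' @export
wncc_scores <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  sq <- net
  sq$weight <- net$weight^2
  wnc_scores(sq)
}

# TRUE when no pair of node-disjoint edges exists: a family of pairwise-
# intersecting edges is either a star (all edges share one node) or sits
# inside a triangle (at most 3 distinct nodes).
no_disjoint_pair <- function(net) {
  e <- n_edges(net)
  if (e < 2L) return(TRUE)
  touched <- unique(c(net$from, net$to))
  if (length(touched) <= 3L) return(TRUE)
  deg <- node_degrees(net)
  max(deg) == e
}

# Permuted weight vector for sample `sample_index` (0-based), fully
# determined by (config$seed, sample_index). Both permute_weights() and
# empirical_pvalues() draw their null samples from here.
null_weights <- function(net, config, sample_index) {
  e <- n_edges(net)
  set.seed(derive_seed(config$seed, sample_index))
  if (config$mode == "shuffle") {
    return(net$weight[sample.int(e)])
  }
  if (no_disjoint_pair(net)) {
    stop("swap mode requires at least one pair of node-disjoint edges ",
         "(this network is a star/triangle-like degenerate case); ",
         "use mode = \"shuffle\"")
  }
  n_swaps <- if (identical(config$n_swaps, "auto")) 10L * e else config$n_swaps
  a <- sample.int(e, n_swaps, replace = TRUE)
  b <- sample.int(e, n_swaps, replace = TRUE)
  w <- net$weight
  for (k in seq_len(n_swaps)) {
    i <- a[k]; j <- b[k]
    if (net$from[i] != net$from[j] && net$from[i] != net$to[j] &&
        net$to[i] != net$from[j] && net$to[i] != net$to[j]) {
      tmp <- w[i]; w[i] <- w[j]; w[j] <- tmp
    }
  }
  w
}

#' Generate one permuted null network
#'
#' Returns the network with the same nodes and edges but with the observed
#' weight multiset randomly reassigned to the edges, according to
#' `config$mode`. The sample is fully determined by `(config$seed,
#' sample_index)` and is exactly the sample that [empirical_pvalues()] uses at
#' the same index.
#'
#' @param net A [weighted_network()].
#' @param config A [permutation_config()].
#' @param sample_index Integer in `[0, n_permutations)`.
#' @return A [weighted_network()] with permuted weights.
#' @export
permute_weights <- function(net, config, sample_index) {
  stopifnot(inherits(net, "weighted_network"),
            inherits(config, "permutation_config"))
  sample_index <- as.integer(sample_index)
  if (is.na(sample_index) || sample_index < 0L ||
      sample_index >= config$n_permutations) {
    stop("'sample_index' must lie in [0, n_permutations)")
  }
  out <- net
  out$weight <- null_weights(net, config, sample_index)
  out
}

# N x E incidence matrix: column e has 1s at the two endpoints of edge e,
# so (B %*% w) is the WNC vector. Observed scores are computed through the
# same product as null scores, keeping floating-point summation order
# identical on both sides of the >= comparison.
incidence_matrix <- function(net) {
  e <- n_edges(net)
  Matrix::sparseMatrix(
    i = c(net$from, net$to), j = c(seq_len(e), seq_len(e)), x = 1,
    dims = c(length(net$nodes), e)
  )
}

#' Empirical permutation P-values for connectivity scores
#'
#' For each gene, the proportion of permuted samples whose null score is
#' greater than or equal to the observed score. Ties count against
#' significance (the comparison is inclusive), and with the default plain
#' proportion estimator P = 0 is attainable when the observed score beats
#' every null sample.
#'
#' @param net A [weighted_network()].
#' @param config A [permutation_config()].
#' @param score_fn One of `"wnc"`, `"wncb"`, `"wncc"`.
#' @return Named numeric vector of nominal P-values over `net$nodes`.
#' @export
empirical_pvalues <- function(net, config, score_fn = c("wnc", "wncb", "wncc")) {
  stopifnot(inherits(net, "weighted_network"),
            inherits(config, "permutation_config"))
  score_fn <- match.arg(score_fn)
  n <- length(net$nodes)
  e <- n_edges(net)
  if (e == 0L) stop("network has no edges")
  deg <- node_degrees(net)
  if (score_fn == "wncb" && any(deg == 0L)) {
    stop("wncb is undefined for isolated node(s): ",
         paste(utils::head(net$nodes[deg == 0L], 5L), collapse = ", "))
  }
  B <- incidence_matrix(net)
  w <- if (score_fn == "wncc") net$weight^2 else net$weight
  obs <- as.vector(B %*% w)
  if (score_fn == "wncb") obs <- obs / deg
  nperm <- config$n_permutations
  counts <- numeric(n)
  if (config$mode == "shuffle") {
    chunk <- max(1L, min(nperm, as.integer(2e6 / e) + 1L, 1000L))
    i0 <- 0L
    while (i0 < nperm) {
      k <- min(chunk, nperm - i0)
      W <- matrix(0, e, k)
      for (s in seq_len(k)) {
        set.seed(derive_seed(config$seed, i0 + s - 1L))
        W[, s] <- w[sample.int(e)]
      }
      S <- as.matrix(B %*% W)
      if (score_fn == "wncb") S <- S / deg
      counts <- counts + rowSums(S >= obs)
      i0 <- i0 + k
    }
  } else {
    for (i in seq_len(nperm) - 1L) {
      wp <- null_weights(net, config, i)
      if (score_fn == "wncc") wp <- wp^2
      s <- as.vector(B %*% wp)
      if (score_fn == "wncb") s <- s / deg
      counts <- counts + (s >= obs)
    }
  }
  p <- if (config$pseudocount) (counts + 1) / (nperm + 1) else counts / nperm
  names(p) <- net$nodes
  p
}

#' Bonferroni correction
#'
#' `min(1, p * m)` per gene, with `m` the number of genes submitted for
#' testing (defaulting to the number of P-values supplied).
#'
#' @param p Numeric vector of nominal P-values in \[0, 1\] (names preserved).
#' @param m Positive integer multiplicity.
#' @return Adjusted P-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("P-values must lie in [0, 1]")
  }
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("'m' must be a positive integer")
  out <- stats::p.adjust(p, method = "bonferroni", n = max(m, length(p)))
  if (m < length(p)) out <- pmin(1, p * m)  # p.adjust requires n >= length(p)
  out
}

#' Run the full WNC hub-detection analysis
#'
#' Computes WNC, WNCB and WNCC for every node, estimates the WNC empirical
#' P-value by permutation, applies the Bonferroni correction over the genes
#' tested, flags genes with adjusted P below `alpha`, and ranks the table by
#' ascending adjusted P, ties broken by descending WNC and then gene id.
#'
#' @param net A [weighted_network()].
#' @param config A [permutation_config()].
#' @param alpha Significance cutoff on the adjusted P-value (default 0.05).
#' @param genes Optional character vector restricting the test to a subset of
#'   nodes; the Bonferroni multiplicity is then the subset size. All genes
#'   must be network nodes.
#' @return A data frame of class `wnc_result` with columns `gene_id`, `wnc`,
#'   `wncb`, `wncc`, `p_nominal`, `p_adjusted`, `rank`, `significant`, ordered
#'   by `rank`.
#' @export
run_wnc <- function(net, config = permutation_config(), alpha = 0.05,
                    genes = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  if (!is.null(genes)) {
    genes <- as.character(genes)
    missing <- setdiff(genes, net$nodes)
    if (length(missing)) {
      stop("gene(s) absent from the network: ",
           paste(utils::head(missing, 10L), collapse = ", "))
    }
  }
  wnc <- wnc_scores(net)
  deg <- node_degrees(net)
  wncb <- wnc / deg
  wncb[deg == 0L] <- NA_real_  # isolated nodes have no mean incident weight
  wncc <- wncc_scores(net)
  p <- empirical_pvalues(net, config, "wnc")
  keep <- if (is.null(genes)) net$nodes else genes
  m <- length(keep)
  res <- data.frame(
    gene_id = keep,
    wnc = unname(wnc[keep]),
    wncb = unname(wncb[keep]),
    wncc = unname(wncc[keep]),
    p_nominal = unname(p[keep]),
    stringsAsFactors = FALSE
  )
  res$p_adjusted <- bonferroni_adjust(res$p_nominal, m)
  ord <- order(res$p_adjusted, -res$wnc, res$gene_id)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  res$significant <- as.integer(res$p_adjusted < alpha)
  rownames(res) <- NULL
  class(res) <- c("wnc_result", "data.frame")
  res
}

#' Spearman rank concordance between two score vectors
#'
#' Spearman rank correlation with average-rank tie handling, used to compare
#' gene rankings produced by alternative weight aggregations (e.g. WNC vs
#' WNCB). Both vectors must be named over the identical gene set.
#'
#' @param scores_a,scores_b Named numeric vectors over the same genes.
#' @return Spearman correlation in \[-1, 1\].
#' @export
rank_concordance <- function(scores_a, scores_b) {
  if (is.null(names(scores_a)) || is.null(names(scores_b)) ||
      !setequal(names(scores_a), names(scores_b)) ||
      length(scores_a) != length(scores_b)) {
    stop("'scores_a' and 'scores_b' must be named over the identical gene set")
  }
  stats::cor(scores_a, scores_b[names(scores_a)], method = "spearman")
}

#' Write a WNC result table as TSV
#'
#' Scores and P-values are printed with 6 significant digits; P-values below
#' 1e-4 switch to scientific notation.
#'
#' @param res A `wnc_result` data frame from [run_wnc()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wnc_results <- function(res, path) {
  stopifnot(inherits(res, "wnc_result"))
  lines <- c(
    "gene_id\twnc\twncb\twncc\tp_nominal\tp_adjusted\trank\tsignificant",
    sprintf("%s\t%.6g\t%.6g\t%.6g\t%.6g\t%.6g\t%d\t%d",
            res$gene_id, res$wnc, res$wncb, res$wncc,
            res$p_nominal, res$p_adjusted, res$rank, res$significant)
  )
  writeLines(lines, path)
  invisible(path)
}
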