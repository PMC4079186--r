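# adjacency list over node indices
adjacency_list <- function(net) {
  n <- length(net$nodes)
  adj <- vector("list", n)
  for (k in seq_along(net$from)) {
    i <- net$from[k]; j <- net$to[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# BFS distances from source s; unreachable nodes get NA
bfs_distances <- function(adj, s, n) {
  d <- rep(NA_integer_, n)
  d[s] <- 0L
  queue <- s
  while (length(queue)) {
    u <- queue[1L]
    queue <- queue[-1L]
    for (v in adj[[u]]) {
      if (is.na(d[v])) {
        d[v] <- d[u] + 1L
        queue <- c(queue, v)
      }
    }
  }
  d
}

#' Node degree
#'
#' Number of incident edges per node of a binary network. The type guarantees
#' degree of at least 1, so the reported minimum is 1.
#'
#' @param net A [binary_network()].
#' @return Named integer vector over `net$nodes`.
#' @export
degree <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  d <- node_degrees(net)
  names(d) <- net$nodes
  d
}

#' Closeness centrality
#'
#' For node `i`, the inverse of the sum of unweighted shortest-path distances
#' from `i` to every other node in `i`'s connected component. Computing within
#' the component means nodes of small disconnected subgraphs can report
#' relatively high closeness — a known caveat of this measure.
#'
#' @param net A [binary_network()].
#' @return Named numeric vector over `net$nodes`, values in (0, 1\].
#' @export
closeness <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  n <- length(net$nodes)
  adj <- adjacency_list(net)
  out <- vapply(seq_len(n), function(s) {
    d <- bfs_distances(adj, s, n)
    1 / sum(d[-s], na.rm = TRUE)
  }, 0)
  names(out) <- net$nodes
  out
}

#' Betweenness centrality
#'
#' For node `i`, the sum over unordered pairs `{j, k}` (both distinct from
#' `i`, within `i`'s component) of the fraction of shortest `j`-`k` paths that
#' pass through `i`. Computed with Brandes' accumulation over breadth-first
#' shortest-path DAGs. The raw (unnormalized) value is returned by default;
#' `normalized = TRUE` divides by `choose(n - 1, 2)`, the number of pairs a
#' node could possibly bridge in an `n`-node network — a monotone rescaling
#' that leaves any percentile-based gene selection unchanged.
#'
#' @param net A [binary_network()].
#' @param normalized Divide by `choose(n - 1, 2)`? Default `FALSE`.
#' @return Named numeric vector over `net$nodes`.
#' @export
betweenness <- function(net, normalized = FALSE) {
  stopifnot(inherits(net, "binary_network"))
  n <- length(net$nodes)
  adj <- adjacency_list(net)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    # single-source shortest paths (BFS), counting geodesics
    sigma <- numeric(n); sigma[s] <- 1
    d <- rep(-1L, n); d[s] <- 0L
    preds <- vector("list", n)
    queue <- integer(0); queue[1L] <- s
    head <- 1L; tail <- 1L
    order_visited <- integer(0)
    while (head <= tail) {
      u <- queue[head]; head <- head + 1L
      order_visited <- c(order_visited, u)
      for (v in adj[[u]]) {
        if (d[v] < 0L) {
          d[v] <- d[u] + 1L
          tail <- tail + 1L
          queue[tail] <- v
        }
        if (d[v] == d[u] + 1L) {
          sigma[v] <- sigma[v] + sigma[u]
          preds[[v]] <- c(preds[[v]], u)
        }
      }
    }
    # dependency accumulation in reverse BFS order
    delta <- numeric(n)
    for (v in rev(order_visited)) {
      for (u in preds[[v]]) {
        delta[u] <- delta[u] + sigma[u] / sigma[v] * (1 + delta[v])
      }
      if (v != s) bc[v] <- bc[v] + delta[v]
    }
  }
  bc <- bc / 2  # each unordered pair {j,k} was accumulated from both sources
  if (normalized) bc <- bc / choose(n - 1, 2)
  names(bc) <- net$nodes
  bc
}

#' Local clustering coefficient
#'
#' Edge density in a node's neighborhood: the number of edges among the
#' node's neighbors divided by `choose(degree, 2)`. Nodes of degree below 2
#' have an undefined denominator and are reported as 0, the common tool
#' convention.
#'
#' @param net A [binary_network()].
#' @return Named numeric vector over `net$nodes`, values in \[0, 1\].
#' @export
clustering_coefficient <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  n <- length(net$nodes)
  adj <- adjacency_list(net)
  nbr <- lapply(adj, function(x) x %||% integer(0))
  out <- vapply(seq_len(n), function(i) {
    ni <- nbr[[i]]
    k <- length(ni)
    if (k < 2L) return(0)
    links <- sum(vapply(ni, function(j) sum(nbr[[j]] %in% ni), 0L)) / 2
    links / choose(k, 2)
  }, 0)
  names(out) <- net$nodes
  out
}

#' All four classical centralities in one table
#'
#' @param net A [binary_network()].
#' @return Data frame with columns `gene_id`, `degree`, `closeness`,
#'   `betweenness`, `clustering`, rows ordered by ascending gene id.
#' @export
centrality_table <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  tab <- data.frame(
    gene_id = net$nodes,
    degree = unname(degree(net)),
    closeness = unname(closeness(net)),
    betweenness = unname(betweenness(net)),
    clustering = unname(clustering_coefficient(net)),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write a centrality table as TSV
#'
#' @param tab Data frame from [centrality_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_centrality_table <- function(tab, path) {
  lines <- c(
    "gene_id\tdegree\tcloseness\tbetweenness\tclustering",
    sprintf("%s\t%d\t%.6g\t%.6g\t%.6g",
            tab$gene_id, tab$degree, tab$closeness, tab$betweenness,
            tab$clustering)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Select top-scoring genes by percentile
#'
#' Returns the genes whose score is greater than or equal to the nearest-rank
#' percentile of the score distribution — the same convention as
#' [threshold_network()]. With heavy ties the returned set can exceed
#' `(1 - percentile)` of the genes; with all scores equal every gene is
#' returned.
#'
#' @param scores Named numeric vector of gene scores.
#' @param percentile Percentile in (0, 1); default 0.95.
#' @return Character vector of selected gene ids.
#' @export
select_top_percentile <- function(scores, percentile = 0.95) {
  if (length(scores) == 0L) stop("'scores' must be nonempty")
  if (is.null(names(scores))) stop("'scores' must be named by gene id")
  thr <- nearest_rank_percentile(scores, percentile)
  names(scores)[scores >= thr]
}

#' Pairwise overlap of named gene sets
#'
#' Counts `|A intersect B|` for every unordered pair of sets and the
#' intersection of all sets. Zero-overlap pairs are reported, not dropped.
#'
#' @param sets Named list of two or more character vectors.
#' @return List with `pairwise` (data frame `set_a`, `set_b`, `overlap`) and
#'   `common` (character vector of genes present in every set).
#' @export
set_overlap <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || is.null(names(sets)) ||
      any(!nzchar(names(sets)))) {
    stop("'sets' must be a named list of at least 2 gene sets")
  }
  sets <- lapply(sets, unique)
  nm <- names(sets)
  pairs <- utils::combn(seq_along(sets), 2L)
  pairwise <- data.frame(
    set_a = nm[pairs[1L, ]],
    set_b = nm[pairs[2L, ]],
    overlap = apply(pairs, 2L, function(ij) {
      length(intersect(sets[[ij[1L]]], sets[[ij[2L]]]))
    }),
    stringsAsFactors = FALSE
  )
  list(pairwise = pairwise, common = Reduce(intersect, sets))
}
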