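# Independent brute-force oracles and small fixture builders. Everything here
# is deliberately naive (enumeration, DFS, matrix powers) and shares no code
# with the package's implementations.

# quick weighted network from a from/to/weight triple list
make_wnet <- function(from, to, weight, nodes = NULL) {
  weighted_network(
    data.frame(from = from, to = to, weight = weight,
               stringsAsFactors = FALSE),
    nodes = nodes
  )
}

make_bnet <- function(from, to) {
  binary_network(data.frame(from = from, to = to, stringsAsFactors = FALSE))
}

# complete graph on `ids` with the given weight vector, edges in
# (1,2),(1,3)...(1,n),(2,3),... order
make_complete <- function(ids, weights) {
  n <- length(ids)
  pairs <- t(utils::combn(n, 2L))
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  stopifnot(length(weights) == nrow(pairs))
  make_wnet(ids[pairs[, 1L]], ids[pairs[, 2L]], weights, nodes = ids)
}

# all permutations of 1..n as an n! x n matrix (recursive enumeration)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

# exact permutation-null P-values by exhaustive enumeration of every
# weight-to-edge assignment (feasible up to ~7 edges)
exact_enum_pvalues <- function(net, score = c("wnc", "wncc")) {
  score <- match.arg(score)
  w <- if (score == "wncc") net$weight^2 else net$weight
  n <- length(net$nodes)
  e <- length(w)
  inc <- matrix(0, n, e)
  for (k in seq_len(e)) {
    inc[net$from[k], k] <- 1
    inc[net$to[k], k] <- 1
  }
  obs <- as.vector(inc %*% w)
  perms <- all_permutations(e)
  counts <- numeric(n)
  for (r in seq_len(nrow(perms))) {
    counts <- counts + (as.vector(inc %*% w[perms[r, ]]) >= obs)
  }
  stats::setNames(counts / nrow(perms), net$nodes)
}

# adjacency matrix of a binary network
adj_matrix <- function(net) {
  n <- length(net$nodes)
  a <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  for (k in seq_along(net$from)) {
    a[net$from[k], net$to[k]] <- 1L
    a[net$to[k], net$from[k]] <- 1L
  }
  a
}

# all-pairs shortest distances by powers of the adjacency matrix
bf_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(NA_integer_, n, n)
  diag(d) <- 0L
  reach <- diag(n)
  pow <- diag(n)
  for (L in seq_len(n)) {
    pow <- pow %*% a
    newly <- pow > 0 & reach == 0
    d[newly] <- L
    reach[newly] <- 1
  }
  d
}

bf_closeness <- function(net) {
  a <- adj_matrix(net)
  d <- bf_distances(a)
  stats::setNames(
    vapply(seq_len(nrow(a)), function(i) 1 / sum(d[i, -i], na.rm = TRUE), 0),
    net$nodes
  )
}

# betweenness by exhaustive DFS enumeration of all simple paths per pair:
# shortest paths are the minimum-length simple paths
bf_betweenness <- function(net) {
  a <- adj_matrix(net)
  n <- nrow(a)
  nbrs <- lapply(seq_len(n), function(i) which(a[i, ] == 1L))
  paths_between <- function(j, k) {
    found <- list()
    walk <- function(path) {
      u <- path[length(path)]
      if (u == k) {
        found[[length(found) + 1L]] <<- path
        return(invisible())
      }
      for (v in nbrs[[u]]) {
        if (!v %in% path) walk(c(path, v))
      }
    }
    walk(j)
    found
  }
  bc <- numeric(n)
  for (j in seq_len(n - 1L)) {
    for (k in (j + 1L):n) {
      paths <- paths_between(j, k)
      if (!length(paths)) next
      len <- lengths(paths)
      shortest <- paths[len == min(len)]
      total <- length(shortest)
      inner <- unlist(lapply(shortest, function(p) p[-c(1L, length(p))]))
      if (length(inner)) {
        through <- tabulate(inner, nbins = n)
        bc <- bc + through / total
      }
    }
  }
  stats::setNames(bc, net$nodes)
}

bf_clustering <- function(net) {
  a <- adj_matrix(net)
  stats::setNames(
    vapply(seq_len(nrow(a)), function(i) {
      nb <- which(a[i, ] == 1L)
      if (length(nb) < 2L) return(0)
      sum(a[nb, nb]) / 2 / choose(length(nb), 2)
    }, 0),
    net$nodes
  )
}

# exact hypergeometric over-representation P by enumerating all C(N, n)
# selections of the universe (feasible for N <= 12)
bf_hyper_pvalue <- function(N, term_size, n, k_obs) {
  sels <- utils::combn(N, n)
  term <- seq_len(term_size)
  hits <- apply(sels, 2L, function(sel) sum(sel %in% term) >= k_obs)
  mean(hits)
}

# random connected-or-not binary network on up to `max_n` nodes; regenerates
# until every node has degree >= 1 (the type invariant)
random_small_bnet <- function(max_n = 7L) {
  repeat {
    n <- sample(3:max_n, 1L)
    pairs <- t(utils::combn(n, 2L))
    keep <- stats::runif(nrow(pairs)) < 0.5
    if (sum(keep) < 1L) next
    pairs <- pairs[keep, , drop = FALSE]
    deg <- tabulate(c(pairs[, 1L], pairs[, 2L]), nbins = n)
    if (any(deg == 0L)) next
    ids <- sprintf("n%02d", seq_len(n))
    return(make_bnet(ids[pairs[, 1L]], ids[pairs[, 2L]]))
  }
}

# planted-hub fixture at the package's reference conditions
planted_hub_fixture <- function(seed = 7L) {
  spec <- hub_spec(n_genes = 200L, n_samples = 10L, n_hubs = 2L,
                   module_size = 15L, driver_strength = 0.9, noise_sd = 1,
                   seed = seed)
  sim <- generate_expression(spec)
  c(sim, list(spec = spec, net = compute_correlation_network(sim$expr)))
}
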