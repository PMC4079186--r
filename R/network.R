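#' Weighted co-expression network
#'
#' An undirected graph over gene identifiers with one weight in \[0, 1\] per
#' unordered node pair. Self-edges and duplicate pairs are rejected. Networks
#' built by [compute_correlation_network()] are complete graphs; networks read
#' from edge lists may be sparse and may contain isolated nodes only if these
#' are passed explicitly through `nodes`.
#'
#' @param edges A data frame with columns `from`, `to` (character gene ids)
#'   and `weight` (numeric in \[0, 1\]).
#' @param nodes Optional character vector of node identifiers; defaults to the
#'   sorted union of edge endpoints. Must contain every endpoint.
#' @return An object of class `weighted_network` with elements `nodes`
#'   (character), `from`, `to` (integer indices into `nodes`, `from < to`) and
#'   `weight` (numeric).
#' @export
weighted_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges))
  if (!all(c("from", "to", "weight") %in% names(edges))) {
    stop("'edges' must have columns 'from', 'to' and 'weight'")
  }
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  weight <- as.numeric(edges$weight)
  if (anyNA(weight) || any(weight < 0) || any(weight > 1)) {
    bad <- which(is.na(weight) | weight < 0 | weight > 1)
    stop("edge weights must be numeric in [0, 1]; offending edge row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (any(from == to)) {
    stop("self-edges are not allowed (e.g. node '", from[from == to][1L], "')")
  }
  if (is.null(nodes)) {
    nodes <- sort(unique(c(from, to)))
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicate node identifiers")
    missing <- setdiff(c(from, to), nodes)
    if (length(missing)) {
      stop("edge endpoints absent from 'nodes': ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
  }
  i <- match(from, nodes)
  j <- match(to, nodes)
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  key <- (i - 1) * length(nodes) + j
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop("duplicate edge for pair {", nodes[i[d]], ", ", nodes[j[d]], "}")
  }
  structure(
    list(nodes = nodes, from = i, to = j, weight = weight),
    class = "weighted_network"
  )
}

#' Binary (unweighted) co-expression network
#'
#' The thresholded counterpart of a [weighted_network()]: edges are present or
#' absent, and every node has degree at least 1 (isolated nodes are dropped at
#' construction, mirroring the node loss observed when a correlation network
#' is thresholded).
#'
#' @param edges Data frame with character columns `from` and `to`.
#' @return An object of class `binary_network` with elements `nodes`, `from`
#'   and `to` (integer indices, `from < to`).
#' @export
binary_network <- function(edges) {
  wn <- weighted_network(cbind(edges[c("from", "to")], weight = 0))
  structure(list(nodes = wn$nodes, from = wn$from, to = wn$to),
            class = "binary_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("Weighted network:", length(x$nodes), "nodes,", length(x$weight),
      "edges; weight range [",
      if (length(x$weight)) sprintf("%.4g, %.4g", min(x$weight), max(x$weight))
      else "-",
      "]\n")
  invisible(x)
}

#' @export
print.binary_network <- function(x, ...) {
  cat("Binary network:", length(x$nodes), "nodes,", length(x$from), "edges\n")
  invisible(x)
}

n_edges <- function(net) length(net$from)

# degree vector over net$nodes (works for both network classes)
node_degrees <- function(net) {
  tabulate(c(net$from, net$to), nbins = length(net$nodes))
}

#' Threshold a weighted network into a binary network
#'
#' Retains exactly the edges whose weight is greater than or equal to the
#' nearest-rank percentile of the weight multiset (see
#' [nearest_rank_percentile()]); ties at the threshold are all kept. Nodes
#' left with no retained edge are removed.
#'
#' @param net A [weighted_network()] with at least one edge.
#' @param percentile Percentile in (0, 1); default 0.95, i.e. edges at or
#'   above the 95th percentile of observed absolute correlations are kept.
#' @return A [binary_network()].
#' @export
threshold_network <- function(net, percentile = 0.95) {
  stopifnot(inherits(net, "weighted_network"))
  if (n_edges(net) == 0L) stop("network has no edges to threshold")
  thr <- nearest_rank_percentile(net$weight, percentile)
  keep <- net$weight >= thr
  edges <- data.frame(
    from = net$nodes[net$from[keep]],
    to = net$nodes[net$to[keep]],
    stringsAsFactors = FALSE
  )
  binary_network(edges)
}

#' Read a weighted network from an edge-list file
#'
#' Accepts a 3-column tab-separated edge list (`gene1 TAB gene2 TAB weight`)
#' or a SIF file (`gene1 TAB relation TAB gene2`). SIF input is only accepted
#' together with a 4th weight column or a `uniform_weight`, since SIF itself
#' carries no weights.
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"sif"`.
#' @param uniform_weight Single weight in \[0, 1\] assigned to every SIF edge
#'   when no weight column is present.
#' @param header Does the file start with a header line? Default `FALSE`.
#' @return A [weighted_network()].
#' @export
read_weighted_network <- function(path, format = c("tsv", "sif"),
                                  uniform_weight = NULL, header = FALSE) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (header) lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no edges in '", path, "'")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  offset <- as.integer(header)
  if (format == "tsv") {
    bad <- which(nf < 3L)
    if (length(bad)) {
      stop("line ", bad[1L] + offset, " of '", path,
           "': expected 3 tab-separated fields (gene1, gene2, weight)")
    }
    g1 <- vapply(fields, `[[`, "", 1L)
    g2 <- vapply(fields, `[[`, "", 2L)
    w <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  } else {
    bad <- which(nf < 3L)
    if (length(bad)) {
      stop("line ", bad[1L] + offset, " of '", path,
           "': expected SIF fields (gene1, relation, gene2)")
    }
    g1 <- vapply(fields, `[[`, "", 1L)
    g2 <- vapply(fields, `[[`, "", 3L)
    if (any(nf >= 4L)) {
      w <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
    } else if (!is.null(uniform_weight)) {
      w <- rep(as.numeric(uniform_weight), length(g1))
    } else {
      stop("SIF input carries no weights: supply a 4th weight column or ",
           "'uniform_weight'")
    }
  }
  bad <- which(is.na(w) | w < 0 | w > 1)
  if (length(bad)) {
    stop("line ", bad[1L] + offset, " of '", path,
         "': malformed edge weight (must be numeric in [0, 1])")
  }
  weighted_network(data.frame(from = g1, to = g2, weight = w,
                              stringsAsFactors = FALSE))
}

#' Write a weighted network as a 3-column TSV edge list
#'
#' Weights are written with 17 significant digits so a written network is
#' re-read losslessly (exact double round-trip).
#'
#' @param net A [weighted_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_weighted_network <- function(net, path) {
  stopifnot(inherits(net, "weighted_network"))
  lines <- sprintf("%s\t%s\t%.17g",
                   net$nodes[net$from], net$nodes[net$to], net$weight)
  writeLines(lines, path)
  invisible(path)
}

#' Read a binary network from a 2-column TSV edge list
#'
#' @param path File path.
#' @param header Does the file start with a header line? Default `FALSE`.
#' @return A [binary_network()].
#' @export
read_binary_network <- function(path, header = FALSE) {
  lines <- readLines(path)
  if (header) lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no edges in '", path, "'")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) {
    stop("line ", bad[1L] + as.integer(header), " of '", path,
         "': expected 2 tab-separated fields (gene1, gene2)")
  }
  binary_network(data.frame(
    from = vapply(fields, `[[`, "", 1L),
    to = vapply(fields, `[[`, "", 2L),
    stringsAsFactors = FALSE
  ))
}

#' Write a binary network
#'
#' `format = "tsv"` writes a 2-column edge list; `format = "sif"` writes
#' Cytoscape-compatible SIF with the relation token `"co"`.
#'
#' @param net A [binary_network()].
#' @param path Output file path.
#' @param format `"tsv"` (default) or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_binary_network <- function(net, path, format = c("tsv", "sif")) {
  stopifnot(inherits(net, "binary_network"))
  format <- match.arg(format)
  lines <- if (format == "tsv") {
    sprintf("%s\t%s", net$nodes[net$from], net$nodes[net$to])
  } else {
    sprintf("%s\tco\t%s", net$nodes[net$from], net$nodes[net$to])
  }
  writeLines(lines, path)
  invisible(path)
}
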