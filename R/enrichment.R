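#' Annotation map for gene-set enrichment
#'
#' A collection of terms, each a set of annotated genes, together with the
#' gene universe the enrichment test conditions on. The universe should be the
#' sampling frame the selection was drawn from — for genes selected from a
#' co-expression network, the network's gene set, not the genome. Annotations
#' are restricted to the universe at construction; terms left empty are
#' rejected, since a term with no testable gene cannot be enriched.
#'
#' @param terms Named list of character vectors (term id -> gene ids).
#' @param universe Character vector of gene ids; defaults to the union of all
#'   annotated genes.
#' @return Object of class `annotation_map` with elements `terms` and
#'   `universe`.
#' @export
annotation_map <- function(terms, universe = NULL) {
  if (!is.list(terms) || length(terms) == 0L || is.null(names(terms)) ||
      any(!nzchar(names(terms))) || anyDuplicated(names(terms))) {
    stop("'terms' must be a nonempty list with unique nonempty names")
  }
  terms <- lapply(terms, function(g) unique(as.character(g)))
  if (is.null(universe)) {
    universe <- sort(unique(unlist(terms, use.names = FALSE)))
  } else {
    universe <- unique(as.character(universe))
    terms <- lapply(terms, intersect, y = universe)
  }
  empty <- names(terms)[lengths(terms) == 0L]
  if (length(empty)) {
    stop("term(s) with no annotated gene in the universe: ",
         paste(utils::head(empty, 5L), collapse = ", "))
  }
  structure(list(terms = terms, universe = universe),
            class = "annotation_map")
}

#' Read a GMT annotation file
#'
#' One gene set per line: term id, description, then member genes,
#' tab-separated. Terms with no member genes are rejected.
#'
#' @param path File path.
#' @param universe Optional gene universe passed to [annotation_map()].
#' @return An [annotation_map()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no gene sets in '", path, "'")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop("line ", bad[1L], " of '", path,
         "': GMT lines need term, description and at least one gene")
  }
  terms <- lapply(fields, function(f) f[-(1:2)])
  names(terms) <- vapply(fields, `[[`, "", 1L)
  annotation_map(terms, universe)
}

#' Fisher-exact gene-set over-representation test
#'
#' For each term, tests whether the selected genes overlap the term's
#' annotated genes more than expected under hypergeometric sampling from the
#' universe. With universe size `N`, selection size `n`, term size `K` and
#' overlap `k`, the one-sided P-value is the upper hypergeometric tail
#' `P(X >= k)` — the one-sided Fisher exact test for over-representation.
#' Depletion is not tested.
#'
#' @param selected Character vector of selected genes; must be a nonempty
#'   subset of the universe.
#' @param annot An [annotation_map()].
#' @param correction `"bonferroni"` (default; over the number of terms tested)
#'   or `"none"`.
#' @return Data frame of class `enrichment_table` with columns `term_id`, `k`
#'   (overlap), `K` (term size), `n` (selection size), `N` (universe size),
#'   `p`, `p_adjusted`, ordered by ascending `p` then term id.
#' @export
fisher_enrichment <- function(selected, annot,
                              correction = c("bonferroni", "none")) {
  stopifnot(inherits(annot, "annotation_map"))
  correction <- match.arg(correction)
  selected <- unique(as.character(selected))
  if (length(selected) == 0L) stop("'selected' must be nonempty")
  outside <- setdiff(selected, annot$universe)
  if (length(outside)) {
    stop("selected gene(s) outside the universe: ",
         paste(utils::head(outside, 10L), collapse = ", "))
  }
  N <- length(annot$universe)
  n <- length(selected)
  K <- lengths(annot$terms)
  k <- vapply(annot$terms, function(g) length(intersect(selected, g)), 0L)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  p_adj <- switch(correction,
                  bonferroni = bonferroni_adjust(p, length(p)),
                  none = p)
  res <- data.frame(
    term_id = names(annot$terms),
    k = unname(k), K = unname(K), n = n, N = N,
    p = unname(p), p_adjusted = unname(p_adj),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_table", "data.frame")
  res
}

#' Write an enrichment table as TSV
#'
#' @param res An `enrichment_table` from [fisher_enrichment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(res, path) {
  stopifnot(inherits(res, "enrichment_table"))
  lines <- c(
    "term_id\tk\tK\tn\tN\tp\tp_adjusted",
    sprintf("%s\t%d\t%d\t%d\t%d\t%.6g\t%.6g",
            res$term_id, res$k, res$K, res$n, res$N, res$p, res$p_adjusted)
  )
  writeLines(lines, path)
  invisible(path)
}
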