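#' Read a gene expression matrix from TSV
#'
#' Expects a header row of sample identifiers and one row per gene, the first
#' column holding the gene identifier and the remaining columns tab-delimited
#' expression values (log-scale assumed but not enforced). Missing values,
#' duplicated gene or sample identifiers, and fewer than 3 samples are all
#' rejected at load time: Pearson correlation is degenerate below 3 samples,
#' and no imputation rule is applied silently.
#'
#' @param path File path.
#' @return A numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids).
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file must have a gene id column plus samples")
  genes <- as.character(df[[1L]])
  values <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes
  validate_expression(values)
  values
}

#' Validate an expression matrix
#'
#' Checks the invariants assumed by [compute_correlation_network()]: a numeric
#' genes-by-samples matrix with unique gene and sample identifiers, at least 3
#' samples, and no missing values.
#'
#' @param expr Numeric matrix with gene rownames and sample colnames.
#' @return `expr`, invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression data must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(expr)) || anyDuplicated(rownames(expr))) {
    stop("gene identifiers (rownames) must be present and unique")
  }
  if (!is.null(colnames(expr)) && anyDuplicated(colnames(expr))) {
    stop("sample identifiers (colnames) must be unique")
  }
  if (ncol(expr) < 3L) {
    stop("at least 3 samples are required (got ", ncol(expr), ")")
  }
  if (anyNA(expr)) {
    bad <- rownames(expr)[unique(which(is.na(expr), arr.ind = TRUE)[, 1L])]
    stop("missing expression values for gene(s): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         "; remove or impute them before loading")
  }
  invisible(expr)
}

#' Build the complete absolute-Pearson co-expression network
#'
#' Computes the Pearson correlation between every pair of gene expression
#' profiles and uses its absolute value as the edge weight, so that strong
#' negative co-expression counts the same as strong positive co-expression.
#' The result is a complete weighted graph: `N * (N - 1) / 2` edges for `N`
#' genes. Genes whose profile has zero variance have no defined correlation
#' and are an error rather than a silent zero, since silent zeros would
#' corrupt the hub ranking.
#'
#' @param expr Numeric genes-by-samples matrix (see [validate_expression()]).
#' @return A complete [weighted_network()] over the genes of `expr`.
#' @export
compute_correlation_network <- function(expr) {
  validate_expression(expr)
  if (nrow(expr) < 2L) stop("at least 2 genes are required")
  v <- apply(expr, 1L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance (constant) expression profile for gene(s): ",
         paste(utils::head(rownames(expr)[v == 0], 5L), collapse = ", "))
  }
  cm <- abs(stats::cor(t(expr)))
  # |r| can exceed 1 by an ulp; clamp so the weight invariant holds exactly
  cm[cm > 1] <- 1
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  weighted_network(
    data.frame(from = rownames(expr)[ut[, 1L]],
               to = rownames(expr)[ut[, 2L]],
               weight = cm[ut],
               stringsAsFactors = FALSE),
    nodes = rownames(expr)
  )
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: header row of sample ids, first column
#' `gene_id`, full-precision values.
#'
#' @param expr Numeric genes-by-samples matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  samples <- colnames(expr) %||% paste0("S", seq_len(ncol(expr)))
  header <- paste(c("gene_id", samples), collapse = "\t")
  rows <- vapply(seq_len(nrow(expr)), function(i) {
    paste(c(rownames(expr)[i], sprintf("%.17g", expr[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}
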