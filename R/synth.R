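#' Specification for a synthetic expression matrix with planted hub modules
#'
#' Describes a genes-by-samples matrix in which a few "hub modules" — groups
#' of genes all driven by a shared latent factor — are embedded in a
#' background of independent noise genes. Each module gene is
#' `a * driver + noise_sd * eps` with `eps` standard normal and
#' `a = noise_sd * s / sqrt(1 - s^2)`, so its population correlation with the
#' latent driver is exactly `s = driver_strength` regardless of `noise_sd`,
#' and the within-module pairwise correlation is `s^2`. Background genes are
#' `noise_sd * eps`. The defaults mirror the scale of small multi-condition
#' expression studies: around ten samples and a few hundred genes.
#'
#' @param n_genes Total number of genes.
#' @param n_samples Number of samples (default 10).
#' @param n_hubs Number of planted modules.
#' @param module_size Genes per module; `n_hubs * module_size <= n_genes`.
#' @param driver_strength Target absolute correlation of module genes to their
#'   latent driver, strictly between 0 and 1.
#' @param noise_sd Standard deviation of the additive noise (default 1).
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @return Object of class `hub_spec`.
#' @export
hub_spec <- function(n_genes, n_samples = 10L, n_hubs, module_size,
                     driver_strength, noise_sd = 1, seed = 1L) {
  n_genes <- as.integer(n_genes); n_samples <- as.integer(n_samples)
  n_hubs <- as.integer(n_hubs); module_size <- as.integer(module_size)
  if (n_genes < 2L) stop("'n_genes' must be at least 2")
  if (n_samples < 3L) stop("'n_samples' must be at least 3")
  if (n_hubs < 0L || module_size < 0L) {
    stop("'n_hubs' and 'module_size' must be nonnegative")
  }
  if (n_hubs > 0L && module_size < 2L) {
    stop("'module_size' must be at least 2 when modules are planted")
  }
  if (n_hubs * module_size > n_genes) {
    stop("'n_hubs' * 'module_size' must not exceed 'n_genes'")
  }
  if (!is.numeric(driver_strength) || driver_strength <= 0 ||
      driver_strength >= 1) {
    stop("'driver_strength' must lie strictly between 0 and 1")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop("'noise_sd' must be positive")
  }
  structure(
    list(n_genes = n_genes, n_samples = n_samples, n_hubs = n_hubs,
         module_size = module_size, driver_strength = driver_strength,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "hub_spec"
  )
}

#' Generate a synthetic expression matrix with planted hub modules
#'
#' See [hub_spec()] for the generative model. With `negative_loadings = TRUE`
#' the second half of each module receives a sign-flipped loading, producing
#' strong *negative* within-module correlations and exercising the
#' absolute-value weighting of the network construction.
#'
#' @param spec A [hub_spec()].
#' @param negative_loadings Flip the loading sign for half of each module?
#'   Default `FALSE`.
#' @return List with `expr` (numeric matrix, genes `g001...` by samples
#'   `S01...`) and `labels` (data frame `gene_id`, `is_hub` 0/1, `module_id`,
#'   `NA` for background genes).
#' @export
generate_expression <- function(spec, negative_loadings = FALSE) {
  stopifnot(inherits(spec, "hub_spec"))
  set.seed(spec$seed)
  g <- spec$n_genes; s <- spec$n_samples
  width <- max(3L, nchar(as.character(g)))
  gene_ids <- sprintf(paste0("g%0", width, "d"), seq_len(g))
  sample_ids <- sprintf("S%02d", seq_len(s))
  expr <- matrix(spec$noise_sd * stats::rnorm(g * s), g, s,
                 dimnames = list(gene_ids, sample_ids))
  module_id <- rep(NA_integer_, g)
  a <- spec$noise_sd * spec$driver_strength / sqrt(1 - spec$driver_strength^2)
  for (h in seq_len(spec$n_hubs)) {
    idx <- ((h - 1L) * spec$module_size + 1L):(h * spec$module_size)
    driver <- stats::rnorm(s)
    load <- rep(a, length(idx))
    if (negative_loadings) {
      flip <- seq_along(idx) > length(idx) / 2
      load[flip] <- -a
    }
    expr[idx, ] <- expr[idx, ] + outer(load, driver)
    module_id[idx] <- h
  }
  labels <- data.frame(
    gene_id = gene_ids,
    is_hub = as.integer(!is.na(module_id)),
    module_id = module_id,
    stringsAsFactors = FALSE
  )
  list(expr = expr, labels = labels)
}

#' Generate a random complete weighted network
#'
#' A complete graph on `n_nodes` with i.i.d. edge weights drawn from
#' `weight_sampler` and clipped to \[0, 1\]. With a constant sampler this
#' yields the uniform-weight network on which every permutation P-value is 1 —
#' the canonical degenerate fixture.
#'
#' @param n_nodes Number of nodes (at least 2).
#' @param weight_sampler Function of one argument `n` returning `n` numeric
#'   draws; default `runif`.
#' @param seed Integer seed.
#' @return A complete [weighted_network()] with nodes `v001, v002, ...`.
#' @export
generate_random_network <- function(n_nodes, weight_sampler = stats::runif,
                                    seed = 1L) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 2L) stop("'n_nodes' must be at least 2")
  stopifnot(is.function(weight_sampler))
  set.seed(as.integer(seed))
  e <- n_nodes * (n_nodes - 1L) / 2
  w <- pmin(1, pmax(0, as.numeric(weight_sampler(e))))
  width <- max(3L, nchar(as.character(n_nodes)))
  ids <- sprintf(paste0("v%0", width, "d"), seq_len(n_nodes))
  pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  # upper.tri enumerates column-major; order by (row, col) for readability
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  weighted_network(
    data.frame(from = ids[pairs[, 1L]], to = ids[pairs[, 2L]], weight = w,
               stringsAsFactors = FALSE),
    nodes = ids
  )
}

#' Write the planted-hub ground-truth labels as TSV
#'
#' @param labels Data frame from [generate_expression()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hub_labels <- function(labels, path) {
  lines <- c(
    "gene_id\tis_hub\tmodule_id",
    sprintf("%s\t%d\t%s", labels$gene_id, labels$is_hub,
            ifelse(is.na(labels$module_id), "NA", labels$module_id))
  )
  writeLines(lines, path)
  invisible(path)
}
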