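test_that("connectivity scores match closed forms on small graphs", {
  tri <- make_wnet(c("a", "a", "b"), c("b", "c", "c"), rep(0.5, 3))
  expect_equal(wnc_scores(tri), c(a = 1, b = 1, c = 1))
  expect_equal(wncc_scores(tri), c(a = 0.5, b = 0.5, c = 0.5))

  path <- make_wnet(c("A", "B"), c("B", "C"), c(0.3, 0.7))
  expect_equal(wnc_scores(path), c(A = 0.3, B = 1.0, C = 0.7))
  expect_equal(wncb_scores(path), c(A = 0.3, B = 0.5, C = 0.7))
  expect_equal(wncc_scores(path), c(A = 0.09, B = 0.58, C = 0.49))

  # complete graph, all weights w: wnc = (N-1)w, wncb = w, wncc = w * wnc
  for (n in c(4L, 9L)) {
    w <- 0.37
    net <- make_complete(sprintf("v%02d", 1:n), rep(w, choose(n, 2)))
    expect_equal(unname(wnc_scores(net)), rep((n - 1) * w, n))
    expect_equal(unname(wncb_scores(net)), rep(w, n))
    expect_equal(wncc_scores(net), w * wnc_scores(net))
  }

  # all weights 1: wncc equals degree
  ones <- make_wnet(c("a", "a", "b"), c("b", "c", "d"), rep(1, 3))
  expect_equal(wncc_scores(ones), c(a = 2, b = 2, c = 1, d = 1))

  # isolated node: wnc 0, wncb errors
  iso <- make_wnet("a", "b", 0.4, nodes = c("a", "b", "z"))
  expect_equal(wnc_scores(iso)[["z"]], 0)
  expect_error(wncb_scores(iso), "z")
})

test_that("wnc conservation: scores sum to twice the total edge weight", {
  set.seed(21)
  for (rep in 1:5) {
    net <- generate_random_network(sample(5:30, 1), seed = rep)
    expect_equal(sum(wnc_scores(net)), 2 * sum(net$weight))
    config <- permutation_config(n_permutations = 10, seed = rep)
    perm <- permute_weights(net, config, sample_index = rep %% 10L)
    expect_equal(sum(wnc_scores(perm)), 2 * sum(perm$weight))
  }
})

test_that("adding a positive-weight edge strictly increases wnc and wncc", {
  net <- make_wnet(c("a", "b"), c("b", "c"), c(0.2, 0.6))
  plus <- make_wnet(c("a", "b", "a"), c("b", "c", "c"), c(0.2, 0.6, 0.05))
  expect_gt(wnc_scores(plus)[["a"]], wnc_scores(net)[["a"]])
  expect_gt(wncc_scores(plus)[["a"]], wncc_scores(net)[["a"]])
})

test_that("permuted samples preserve node set, topology and weight multiset", {
  net <- generate_random_network(12, seed = 4)
  for (mode in c("shuffle", "swap")) {
    config <- permutation_config(n_permutations = 50, seed = 99, mode = mode)
    for (i in c(0L, 7L, 49L)) {
      perm <- permute_weights(net, config, i)
      expect_identical(perm$nodes, net$nodes)
      expect_identical(perm$from, net$from)
      expect_identical(perm$to, net$to)
      expect_identical(sort(perm$weight), sort(net$weight))
    }
    # determinism: same (seed, index) -> identical sample
    expect_identical(permute_weights(net, config, 7L)$weight,
                     permute_weights(net, config, 7L)$weight)
  }
})

test_that("uniform weights make permutation a no-op and all P-values 1", {
  net <- generate_random_network(8, weight_sampler = function(n) rep(0.5, n),
                                 seed = 1)
  config <- permutation_config(n_permutations = 200, seed = 3)
  expect_identical(permute_weights(net, config, 0L)$weight, net$weight)
  p <- empirical_pvalues(net, config, "wnc")
  expect_true(all(p == 1))
})

test_that("swap mode rejects graphs with no node-disjoint edge pair", {
  star <- make_wnet(rep("hub", 4), paste0("leaf", 1:4), c(0.1, 0.2, 0.3, 0.4))
  config <- permutation_config(n_permutations = 5, seed = 1, mode = "swap")
  expect_error(permute_weights(star, config, 0L), "shuffle")
  tri <- make_wnet(c("a", "a", "b"), c("b", "c", "c"), c(0.1, 0.2, 0.3))
  expect_error(permute_weights(tri, config, 0L), "shuffle")
  # shuffle mode handles the same graphs fine
  sconfig <- permutation_config(n_permutations = 5, seed = 1)
  expect_silent(p <- permute_weights(star, sconfig, 0L))
})

test_that("swap chain visits exactly the disjoint-pair-reachable assignments,
           near-uniformly", {
  # K4 has three disjoint edge pairs; the transpositions they induce commute,
  # so the reachable set from the identity is a group of 2^3 = 8 assignments
  w <- c(0.05, 0.15, 0.35, 0.55, 0.75, 0.95)
  net <- make_complete(paste0("v", 1:4), w)
  # edge order (1,2),(1,3),(1,4),(2,3),(2,4),(3,4): disjoint index pairs
  gens <- list(c(1L, 6L), c(2L, 5L), c(3L, 4L))
  apply_gen <- function(v, g) { t <- v[g[1]]; v[g[1]] <- v[g[2]]; v[g[2]] <- t; v }
  reachable <- list(w)
  repeat {
    grown <- reachable
    for (v in reachable) for (g in gens) {
      cand <- apply_gen(v, g)
      if (!any(vapply(grown, identical, TRUE, y = cand))) {
        grown <- c(grown, list(cand))
      }
    }
    if (length(grown) == length(reachable)) break
    reachable <- grown
  }
  expect_length(reachable, 8L)

  nsamp <- 4000L
  config <- permutation_config(n_permutations = nsamp, seed = 17,
                               mode = "swap")
  hits <- integer(8L)
  for (i in seq_len(nsamp) - 1L) {
    wp <- permute_weights(net, config, i)$weight
    idx <- which(vapply(reachable, identical, TRUE, y = wp))
    expect_length(idx, 1L)  # every sample is a reachable assignment
    hits[idx] <- hits[idx] + 1L
  }
  expect_gt(stats::chisq.test(hits)$p.value, 1e-4)
})

test_that("empirical P-values follow the inclusive >= proportion definition", {
  # direct check of the estimator on a case small enough to count by hand:
  # null scores {2, 3, 5, 1}, observed 3 -> two of four samples >= observed
  counts <- sum(c(2, 3, 5, 1) >= 3)
  expect_equal(counts / 4, 0.5)

  # the same property through the package on K4: empirical vs exhaustive;
  # dyadic weights make every subset sum distinct and exactly representable,
  # so >= comparisons cannot flip on floating-point rounding
  w <- c(1, 1 / 2, 1 / 4, 1 / 8, 1 / 16, 1 / 32)
  net <- make_complete(paste0("g", 1:4), w)
  exact <- exact_enum_pvalues(net, "wnc")
  nperm <- 50000L
  config <- permutation_config(n_permutations = nperm, seed = 12)
  emp <- empirical_pvalues(net, config, "wnc")
  mcse <- sqrt(exact * (1 - exact) / nperm)
  expect_true(all(abs(emp - exact[names(emp)]) <= 3 * mcse[names(emp)]))

  # wncc-based P-values against the same enumeration oracle
  exact_c <- exact_enum_pvalues(net, "wncc")
  emp_c <- empirical_pvalues(net, config, "wncc")
  mcse_c <- sqrt(exact_c * (1 - exact_c) / nperm)
  expect_true(all(abs(emp_c - exact_c[names(emp_c)]) <=
                    3 * mcse_c[names(emp_c)]))

  # wncb is wnc over a permutation-invariant divisor: identical P-values
  expect_identical(empirical_pvalues(net, config, "wncb"), emp)
})

test_that("pseudocount estimator never reports zero and stays close", {
  net <- make_complete(paste0("g", 1:5), seq(0.05, 1, length.out = 10))
  plain <- empirical_pvalues(net, permutation_config(500, seed = 2), "wnc")
  addone <- empirical_pvalues(
    net, permutation_config(500, seed = 2, pseudocount = TRUE), "wnc")
  expect_true(all(addone > 0))
  expect_equal(addone, (plain * 500 + 1) / 501)
})

test_that("bonferroni adjustment is min(1, p * m) and rejects bad input", {
  expect_equal(bonferroni_adjust(0.0002, 198), 0.0396)
  expect_equal(bonferroni_adjust(0.01, 200), 1.0)
  expect_equal(bonferroni_adjust(0, 12345), 0)
  set.seed(8)
  p <- runif(50)
  for (m in c(1L, 50L, 977L)) {
    expect_equal(bonferroni_adjust(p, m), pmin(1, p * m))
  }
  expect_error(bonferroni_adjust(c(0.1, 1.3)), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(-0.1, 5), "\\[0, 1\\]")
})

test_that("run_wnc produces a complete, deterministically ranked table", {
  net <- generate_random_network(20, seed = 31)
  config <- permutation_config(n_permutations = 400, seed = 5)
  res <- run_wnc(net, config)
  expect_s3_class(res, "wnc_result")
  expect_setequal(res$gene_id, net$nodes)
  expect_true(all(res$p_adjusted >= res$p_nominal))
  expect_true(all(res$p_adjusted <= 1))
  expect_identical(res$rank, seq_len(nrow(res)))
  ord <- order(res$p_adjusted, -res$wnc, res$gene_id)
  expect_identical(ord, seq_len(nrow(res)))
  # wncb = wnc / (N - 1) exactly on a complete graph
  expect_equal(res$wncb, res$wnc / (length(net$nodes) - 1))
  # identical seed -> identical table
  expect_identical(run_wnc(net, config), res)
  # uniform network: nothing significant at any alpha < 1
  uni <- generate_random_network(10, function(n) rep(0.3, n), seed = 1)
  expect_identical(sum(run_wnc(uni, permutation_config(100, seed = 1),
                               alpha = 0.9999)$significant), 0L)
})

test_that("run_wnc restricted to a gene subset adjusts over the subset size", {
  net <- generate_random_network(15, seed = 6)
  config <- permutation_config(n_permutations = 200, seed = 9)
  genes <- net$nodes[c(2, 5, 11)]
  res <- run_wnc(net, config, genes = genes)
  expect_setequal(res$gene_id, genes)
  expect_equal(res$p_adjusted, pmin(1, res$p_nominal * 3))
  expect_error(run_wnc(net, config, genes = c(genes, "nope")), "nope")
})

test_that("rank concordance is Spearman with average-rank ties", {
  ids <- paste0("g", 1:5)
  a <- stats::setNames(c(1, 2, 3, 4, 5), ids)
  expect_equal(rank_concordance(a, a), 1.0)
  expect_equal(rank_concordance(a, stats::setNames(rev(a), ids)), -1.0)
  # d^2 sum = 2 -> 1 - 6*2/(5*24) = 0.9
  b <- stats::setNames(c(1, 3, 2, 4, 5), ids)
  expect_equal(rank_concordance(a, b), 0.9)
  # order-insensitive in the names, error on mismatched sets
  expect_equal(rank_concordance(a, b[c(3, 1, 2, 5, 4)]), 0.9)
  expect_error(rank_concordance(a, stats::setNames(1:5, paste0("x", 1:5))),
               "identical gene set")
})

test_that("wnc and nominal P are anticorrelated on a heterogeneous network", {
  fix <- planted_hub_fixture()
  config <- permutation_config(n_permutations = 300, seed = 2)
  p <- empirical_pvalues(fix$net, config, "wnc")
  s <- wnc_scores(fix$net)
  expect_lt(cor(s, p), 0)
})

test_that("result table TSV uses 6 significant digits and scientific P < 1e-4", {
  dir <- withr::local_tempdir()
  net <- make_complete(paste0("g", 1:4), c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  res <- run_wnc(net, permutation_config(n_permutations = 20, seed = 1))
  res$p_nominal[1] <- 2e-5  # exercise the scientific-notation branch
  res$p_adjusted[1] <- 8e-5
  path <- file.path(dir, "res.tsv")
  write_wnc_results(res, path)
  lines <- readLines(path)
  expect_match(lines[1], "^gene_id\twnc\twncb\twncc\tp_nominal")
  expect_match(lines[2], "2e-05")
  expect_identical(length(lines), 5L)
})
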