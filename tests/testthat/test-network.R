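# small expression fixture with known correlation structure: two blocks of
# strongly co-expressed genes plus independent background genes
blocky_expr <- function(n_block = 4, n_bg = 20, n_tumors = 10, seed = 3,
                        noise = 0.05) {
  set.seed(seed)
  base1 <- rnorm(n_tumors)
  base2 <- rnorm(n_tumors)
  rows <- list()
  for (i in seq_len(n_block)) {
    rows[[length(rows) + 1]] <- 2^(8 + base1 + rnorm(n_tumors, 0, noise))
    rows[[length(rows) + 1]] <- 2^(8 + base2 + rnorm(n_tumors, 0, noise))
  }
  for (i in seq_len(n_bg)) {
    rows[[length(rows) + 1]] <- 2^(8 + rnorm(n_tumors))
  }
  vals <- do.call(rbind, rows)
  ids <- c(sprintf("blk1_%d", seq_len(n_block)), sprintf("blk2_%d", seq_len(n_block)))
  ids <- as.vector(rbind(sprintf("blk1_%d", seq_len(n_block)),
                         sprintf("blk2_%d", seq_len(n_block))))
  ids <- c(ids, sprintf("bg_%02d", seq_len(n_bg)))
  tiny_expr(vals, gene_ids = ids)
}

test_that("collinear and anti-correlated genes land in the right sets", {
  t10 <- sprintf("T%02d", 1:10)
  base <- 2^(8 + seq(-1, 1, length.out = 10))
  vals <- rbind(base, base * 1.5, 2^(16 - log2(base)), 2^rep(8, 10) * (1 + 0.01 * seq(0, 9)))
  expr <- tiny_expr(vals, gene_ids = c("seed", "twin", "mirror", "other"),
                    tumors = t10)
  ns <- neighbor_set(expr, "seed", cutoff = 0.63)
  expect_true("twin" %in% ns$positive)
  expect_true("mirror" %in% ns$negative)
  expect_false("seed" %in% c(ns$positive, ns$negative))
  expect_length(intersect(ns$positive, ns$negative), 0)
})

test_that("neighbor sets equal brute-force correlation thresholding", {
  expr <- blocky_expr(n_bg = 40, seed = 7)
  # reconstruct the matrix independently for the oracle
  em <- dplyr::arrange(expr_means(expr), gene_id, tumor_id)
  wide <- tidyr::pivot_wider(em, names_from = tumor_id, values_from = expr)
  mat <- log2(as.matrix(wide[-1])); rownames(mat) <- wide$gene_id
  ns <- neighbor_set(expr, "blk1_1", cutoff = 0.63)
  seedv <- mat["blk1_1", ]
  for (g in setdiff(rownames(mat), "blk1_1")) {
    r <- cor(mat[g, ], seedv)
    expect_equal(g %in% ns$positive, r >= 0.63, info = g)
    expect_equal(g %in% ns$negative, r <= -0.63, info = g)
    expect_equal(unname(ns$R[g]), r, tolerance = 1e-12)
  }
})

test_that("neighborhood is symmetric between genes", {
  expr <- blocky_expr(seed = 11)
  genes <- unique(expr$gene_id)[1:10]
  sets <- lapply(genes, function(g) neighbor_set(expr, g, cutoff = 0.63))
  names(sets) <- genes
  for (g in genes) {
    for (h in setdiff(genes, g)) {
      expect_equal(h %in% sets[[g]]$positive, g %in% sets[[h]]$positive)
      expect_equal(h %in% sets[[g]]$negative, g %in% sets[[h]]$negative)
    }
  }
})

test_that("sharing significance matches exhaustive enumeration", {
  set.seed(31)
  universe <- 50
  pool <- sprintf("g%02d", seq_len(universe))
  for (i in 1:30) {
    A <- sample(pool, sample(5:20, 1))
    B <- sample(pool, sample(5:20, 1))
    got <- sharing_significance(A, B, universe)
    expect_equal(got$p,
                 oracle_overlap_p(got$shared, length(A), length(B), universe),
                 tolerance = 1e-12)
    expect_equal(got$expected, length(A) * length(B) / universe)
  }
  # disjoint sets: upper tail from zero overlap is certain
  expect_equal(sharing_significance(pool[1:5], pool[6:10], universe)$p, 1)
  # identical small sets: overlap as extreme as possible
  expect_lt(sharing_significance(pool[1:5], pool[1:5], universe)$p, 1e-4)
  expect_error(sharing_significance(pool, pool, 10), "universe")
})

test_that("the sharing network records degrees and signs faithfully", {
  expr <- blocky_expr(n_block = 3, n_bg = 10, seed = 13, noise = 0.01)
  drivers <- c("blk1_1", "blk1_2", "blk1_3")
  sets <- lapply(drivers, function(g) neighbor_set(expr, g, cutoff = 0.63))
  net <- build_sharing_network(sets, display_cutoff = 0.90)
  expect_true(all(drivers %in% igraph::V(net$graph)$name))
  # degree of each driver equals its thresholded neighbor count
  for (i in seq_along(drivers)) {
    n_strong <- sum(abs(sets[[i]]$R) >= 0.90)
    expect_equal(unname(igraph::degree(net$graph, drivers[i])), n_strong)
  }
  # blk2 genes correlate negatively ... or not at all; edge signs match R
  expect_true(all((net$edges$R > 0) == (net$edges$sign == "positive")))

  # with an impossible cutoff the drivers stay isolated
  empty <- build_sharing_network(sets, display_cutoff = 1 + 1e-9)
  expect_equal(igraph::vcount(empty$graph), length(drivers))
  expect_equal(igraph::ecount(empty$graph), 0)
})

test_that("complete-linkage merges match the naive agglomeration", {
  set.seed(17)
  vals <- 2^matrix(rnorm(20 * 10, 8, 1), nrow = 20)
  expr <- tiny_expr(vals)
  hc <- cluster_drivers(expr, sprintf("g%03d", 1:20))
  em <- expr_means(expr)
  wide <- tidyr::pivot_wider(em, names_from = tumor_id, values_from = expr)
  mat <- log2(as.matrix(wide[-1])); rownames(mat) <- wide$gene_id
  d <- as.dist(1 - cor(t(mat[sprintf("g%03d", 1:20), ])))
  expect_equal(hc$height, oracle_complete_linkage_heights(d), tolerance = 1e-12)
  # ultrametric: merge heights never decrease
  expect_true(all(diff(hc$height) >= -1e-12))
})

test_that("perfectly correlated genes merge first, at distance zero", {
  t10 <- sprintf("T%02d", 1:10)
  base <- 2^(8 + seq(-1, 1, length.out = 10))
  vals <- rbind(base, base^1, 2^(16 - log2(base)))
  expr <- tiny_expr(vals, gene_ids = c("a", "b", "anti"), tumors = t10)
  hc <- cluster_drivers(expr, c("a", "b", "anti"))
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  expect_setequal(hc$labels[-hc$merge[1, ]], c("a", "b"))
})

test_that("planted co-expression blocks are recovered at the 2-cluster cut", {
  ok <- 0
  for (s in 1:20) {
    expr <- blocky_expr(n_block = 5, n_bg = 0, seed = 100 + s, noise = 0.1)
    genes <- unique(expr$gene_id)
    hc <- cluster_drivers(expr, genes)
    cut <- stats::cutree(hc, k = 2)
    blk1 <- genes[startsWith(genes, "blk1")]
    blk2 <- genes[startsWith(genes, "blk2")]
    if (length(unique(cut[blk1])) == 1 && length(unique(cut[blk2])) == 1 &&
        unique(cut[blk1]) != unique(cut[blk2])) {
      ok <- ok + 1
    }
  }
  expect_gte(ok, 18)
})

test_that("zero-variance genes are dropped with a warning", {
  t5 <- sprintf("T%02d", 1:5)
  vals <- rbind(2^rnorm(5, 8), rep(64, 5), 2^rnorm(5, 8))
  expr <- tiny_expr(vals, gene_ids = c("a", "flat", "b"), tumors = t5)
  expect_warning(hc <- cluster_drivers(expr, c("a", "flat", "b")), "flat")
  expect_equal(sort(hc$labels), c("a", "b"))
  expect_error(suppressWarnings(cluster_drivers(expr, c("flat", "a"))),
               "at least 2")
})

test_that("dendrograms export to Newick and re-import with the same topology", {
  skip_if_not_installed("ape")
  set.seed(19)
  vals <- 2^matrix(rnorm(6 * 8, 8, 1), nrow = 6)
  expr <- tiny_expr(vals, gene_ids = sprintf("gene%d", 1:6))
  hc <- cluster_drivers(expr, sprintf("gene%d", 1:6))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(hc, path)
  tr <- ape::read.tree(path)
  expect_setequal(tr$tip.label, sprintf("gene%d", 1:6))
})
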