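# Cluster expression summaries, marker/DEG detection, dendrograms.

test_that("cluster expression is the scaled mean within-cell fraction", {
  # one nucleus: gene share 1% -> 10,000 on the per-million scale
  c1 <- cbind(n1 = c(10, 990))
  rownames(c1) <- c("focal", "other")
  ce1 <- cluster_expression(tiny_sce(c1, cluster = "k1"))
  expect_equal(ce1$values["k1", "focal"], 10000)
  # two nuclei with shares 1% and 3% -> mean 2% -> 20,000
  c2 <- cbind(n1 = c(10, 990), n2 = c(30, 970))
  rownames(c2) <- c("focal", "other")
  ce2 <- cluster_expression(tiny_sce(c2, cluster = c("k1", "k1")))
  expect_equal(ce2$values["k1", "focal"], 20000)
  # absent gene -> exactly 0
  c3 <- rbind(c2, silent = c(0, 0))
  ce3 <- cluster_expression(tiny_sce(c3, cluster = c("k1", "k1")))
  expect_identical(ce3$values["k1", "silent"], 0)
})

test_that("cluster expression is invariant to duplicating member cells", {
  set.seed(2)
  counts <- matrix(rpois(50 * 20, 2) + 1, nrow = 50)
  labels <- rep(c("a", "b"), each = 10)
  ce <- cluster_expression(tiny_sce(counts), labels = labels)
  dup <- cluster_expression(tiny_sce(cbind(counts, counts)),
                            labels = c(labels, labels))
  expect_equal(ce$values, dup$values)
  expect_identical(unname(dup$n_cells), 2L * unname(ce$n_cells))
})

test_that("planted markers are recovered one-vs-rest under the stated gates", {
  sim <- simulate_atlas(atlas_sim_config(
    n_species = 1L, n_clusters = 3L, n_genes = 300L,
    n_marker_genes_per_cluster = 6L, marker_fold = 10,
    phenotypes = c(w = 1L), cells_per_replicate = 600L,
    mean_umi_per_cell = 800, seed = 42L))
  mk <- find_markers(sim$species$A)
  for (k in names(sim$truth$true_markers$A)) {
    found <- mk$gene[mk$cluster == k & mk$fdr < 0.05]
    expect_gte(mean(sim$truth$true_markers$A[[k]] %in% found), 0.8)
  }
})

test_that("rank-sum approximation tracks the exact permutation p on a toy", {
  x <- c(1.2, 3.4, 2.2, 0.7, 2.9, 1.9)
  in_a <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  p_impl <- crossatlas:::.ranksum_p(matrix(x, nrow = 1), in_a)
  p_exact <- perm_ranksum_p(x, in_a)
  expect_lt(abs(p_impl - p_exact) / p_exact, 0.10)
})

test_that("down-regulated genes are excluded under positive_only", {
  set.seed(9)
  base <- matrix(rpois(40 * 60, 5), nrow = 40,
                 dimnames = list(sprintf("g%02d", 1:40), NULL))
  base["g01", 1:30] <- 0L   # down in cluster a
  labels <- rep(c("a", "b"), each = 30)
  mk <- find_markers(tiny_sce(base), labels = labels)
  expect_false("g01" %in% mk$gene[mk$cluster == "a"])
  expect_true("g01" %in% mk$gene[mk$cluster == "b"])
})

test_that("tiny clusters are skipped with a warning", {
  counts <- matrix(rpois(20 * 7, 4) + 1, nrow = 20)
  labels <- c(rep("big", 5), "small", "small")
  expect_warning(find_markers(tiny_sce(counts), labels = labels),
                 "fewer than 3|< 3")
})

test_that("marker detection under a global null stays near the nominal FDR", {
  sim <- simulate_atlas(atlas_sim_config(
    n_species = 1L, n_clusters = 1L, n_genes = 2000L,
    n_marker_genes_per_cluster = 0L, phenotypes = c(w = 1L),
    cells_per_replicate = 450L, mean_umi_per_cell = 700, seed = 13L))
  set.seed(14)
  labels <- sample(rep(c("a", "b", "c"), length.out = 450))
  mk <- find_markers(sim$species$A, labels = labels)
  flagged <- sum(mk$fdr < 0.05)
  expect_lte(flagged / 2000, 2 * 0.05)
})

test_that("find_degs applies the FDR, fold and percent-expressed gates", {
  set.seed(21)
  n <- 120
  counts <- matrix(rpois(300 * n, 2), nrow = 300,
                   dimnames = list(sprintf("g%03d", 1:300), NULL))
  labels <- rep(c("x", "y"), each = n / 2)
  # planted 3-fold gene, broadly expressed
  counts["g001", labels == "x"] <- rpois(n / 2, 9)
  # rare gene: huge fold but expressed in ~10% of up-group cells
  counts["g002", ] <- 0L
  hot <- which(labels == "x")[1:6]
  counts["g002", hot] <- 40L
  degs <- find_degs(tiny_sce(counts), labels = labels,
                    group_a = "x", group_b = "y")
  g1 <- degs[degs$gene == "g001", ]
  expect_true(g1$significant)
  expect_identical(g1$up_group, "x")
  expect_gt(g1$fold_change, 1.25)
  g2 <- degs[degs$gene == "g002", ]
  expect_false(g2$significant)     # pct gate: 6/60 = 10% < 20%
  expect_lt(g2$pct_expressing, 0.20)
  expect_error(find_degs(tiny_sce(counts), labels = labels,
                         group_a = "x", group_b = "x"),
               "identical|overlap")
})

test_that("a relabelled null yields (almost) no significant DEGs", {
  sim <- simulate_atlas(atlas_sim_config(
    n_species = 1L, n_clusters = 1L, n_genes = 2000L,
    n_marker_genes_per_cluster = 0L, phenotypes = c(w = 1L),
    cells_per_replicate = 300L, mean_umi_per_cell = 700, seed = 23L))
  set.seed(24)
  labels <- sample(rep(c("a", "b"), length.out = 300))
  degs <- find_degs(sim$species$A, labels = labels,
                    group_a = "a", group_b = "b")
  expect_lte(mean(degs$significant), 0.005)
})

test_that("correlation dendrogram pairs duplicated programs first", {
  set.seed(3)
  prog1 <- rlnorm(120, 0, 1); prog2 <- rlnorm(120, 0, 1)
  vals <- rbind(k1 = prog1 * 1e4, k2 = prog1 * 1e4 * 1.0000001,
                k3 = prog2 * 1e4)
  colnames(vals) <- sprintf("g%03d", 1:120)
  expr <- structure(list(values = vals, n_cells = c(k1 = 5L, k2 = 5L, k3 = 5L)),
                    class = "cluster_expression")
  res <- suppressWarnings(correlation_dendrogram(expr, top_n_genes = 500L,
                                                 bootstrap_reps = 100L))
  # k1 and k2 are siblings with high support
  pair <- ape::extract.clade(res$tree,
                             ape::getMRCA(res$tree, c("k1", "k2")))
  expect_setequal(pair$tip.label, c("k1", "k2"))
  expect_gte(max(res$support, na.rm = TRUE), 0.95)
  # self-correlation distance is exactly zero
  expect_equal(unname(as.matrix(1 - cor(t(vals)))["k1", "k1"]), 0)
})

test_that("dendrogram topology is invariant to cluster input order", {
  set.seed(4)
  vals <- matrix(rlnorm(5 * 200), nrow = 5,
                 dimnames = list(paste0("k", 1:5), sprintf("g%03d", 1:200)))
  mk_expr <- function(v) structure(
    list(values = v, n_cells = setNames(rep(5L, nrow(v)), rownames(v))),
    class = "cluster_expression")
  t1 <- correlation_dendrogram(mk_expr(vals), top_n_genes = 200L,
                               bootstrap_reps = 0L)$tree
  perm <- c(3, 1, 5, 2, 4)
  t2 <- correlation_dendrogram(mk_expr(vals[perm, ]), top_n_genes = 200L,
                               bootstrap_reps = 0L)$tree
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1], 0)
})

test_that("top_n_genes larger than the gene pool warns and uses all genes", {
  vals <- matrix(rlnorm(3 * 50), nrow = 3,
                 dimnames = list(paste0("k", 1:3), sprintf("g%02d", 1:50)))
  expr <- structure(list(values = vals, n_cells = c(k1 = 5L, k2 = 5L, k3 = 5L)),
                    class = "cluster_expression")
  expect_warning(res <- correlation_dendrogram(expr, top_n_genes = 8000L,
                                               bootstrap_reps = 0L),
                 "using all")
  expect_length(res$genes_used, 50L)
})
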