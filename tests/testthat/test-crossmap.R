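# Pseudo-cells, z-transform, neighbour-voting AUROC and the correspondence
# network.

make_random_pcm <- function(n_genes, clusters_sizes, seed, prefix = "d1") {
  set.seed(seed)
  n_pc <- sum(clusters_sizes)
  cl <- rep(names(clusters_sizes), clusters_sizes)
  ids <- sprintf("%s_pc%03d", prefix, seq_len(n_pc))
  z <- matrix(rnorm(n_genes * n_pc), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)), ids))
  structure(list(z = z, cluster = setNames(cl, ids),
                 members = setNames(as.list(paste0(prefix, "_", ids)), ids),
                 stage = "z"),
            class = "pseudo_cells")
}

test_that("pseudo-cells partition clusters into disjoint groups of ten", {
  set.seed(1)
  counts <- matrix(rpois(30 * 40, 3), nrow = 30,
                   dimnames = list(sprintf("g%02d", 1:30),
                                   sprintf("cell%03d", 1:40)))
  labels <- c(rep("a", 25), rep("b", 15))
  pcm <- make_pseudocells(tiny_sce(counts), labels = labels, seed = 3)
  expect_identical(sum(pcm$cluster == "a"), 2L)   # floor(25 / 10)
  expect_identical(sum(pcm$cluster == "b"), 1L)
  expect_identical(unname(pcm$dropped), c(5L, 5L))
  # disjoint membership, conservation of member totals
  all_members <- unlist(pcm$members)
  expect_identical(anyDuplicated(all_members), 0L)
  for (pc in names(pcm$members))
    expect_equal(sum(pcm$counts[, pc]),
                 sum(counts[, colnames(counts) %in% pcm$members[[pc]]]))
})

test_that("ten identical cells give the single-cell CP10K profile", {
  one <- c(3, 7, 0, 10)
  counts <- matrix(rep(one, 10), ncol = 10,
                   dimnames = list(paste0("g", 1:4), paste0("c", 1:10)))
  pcm <- make_pseudocells(tiny_sce(counts), labels = rep("k", 10))
  expect_equal(unname(as.matrix(pcm$cp10k)[, 1]), one / sum(one) * 1e4)
})

test_that("undersized clusters warn; empty output is an error", {
  counts <- matrix(rpois(10 * 12, 3), nrow = 10)
  expect_warning(
    pcm <- make_pseudocells(tiny_sce(counts),
                            labels = c(rep("big", 10), "tiny", "tiny")),
    "tiny")
  expect_true(all(pcm$cluster == "big"))
  expect_error(
    suppressWarnings(make_pseudocells(tiny_sce(counts[, 1:5]),
                                      labels = rep("k", 5))),
    "no cluster")
})

test_that("z-transform uses the population s.d. and zeroes constant genes", {
  pcm <- structure(list(
    counts = NULL,
    cp10k = matrix(c(1, 3, 5, 5), nrow = 2, byrow = TRUE,
                   dimnames = list(c("gA", "gB"), c("p1", "p2"))),
    cluster = c(p1 = "k", p2 = "k"),
    members = list(p1 = "c1", p2 = "c2"), stage = "cp10k"),
    class = "pseudo_cells")
  out <- standardize_pseudocells(pcm, c("gA", "gB"))
  expect_equal(unname(out$z["gA", ]), c(-1, 1))   # population s.d. = 1
  expect_equal(unname(out$z["gB", ]), c(0, 0))    # zero variance
  expect_lt(max(abs(rowMeans(out$z))), 1e-12)
  expect_error(standardize_pseudocells(pcm, character(0)), "empty")
})

test_that("AUROC vote convention: separation, ties, and midranks", {
  f <- crossatlas:::.auroc_from_votes
  expect_equal(f(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(f(rep(0.5, 6), c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)), 0.5)
  expect_equal(f(c(0.3, 0.1, 0.2), c(TRUE, TRUE, FALSE)), 0.5)  # 1 win, 1 loss
  # invariance under strictly monotone transforms of the votes
  set.seed(5)
  v <- rnorm(30); pos <- seq(30) %in% sample(30, 10)
  expect_equal(f(v, pos), f(exp(v), pos))
  expect_equal(f(v, pos), f(rank(v), pos))
})

test_that("auroc_pair equals the exhaustive pair-counting oracle", {
  set.seed(17)
  for (rep in 1:40) {
    sizes_s <- setNames(sample(2:6, 3), c("x", "y", "z"))
    sizes_t <- setNames(sample(2:6, 3), c("x", "y", "z"))
    ps <- make_random_pcm(25, sizes_s, seed = rep, prefix = "s")
    pt <- make_random_pcm(25, sizes_t, seed = rep + 1000, prefix = "t")
    a <- auroc_pair(ps, pt, "x", "y")
    expect_equal(a, oracle_auroc(ps, pt, "x", "y"), tolerance = 1e-12)
    # within-dataset direction with self-exclusion
    aw <- auroc_pair(ps, ps, "x", "y")
    expect_equal(aw, oracle_auroc(ps, ps, "x", "y"), tolerance = 1e-12)
  }
})

test_that("auroc_pair refuses a target dataset without negatives", {
  ps <- make_random_pcm(10, c(x = 3), seed = 1, prefix = "s")
  pt <- make_random_pcm(10, c(x = 3), seed = 2, prefix = "t")
  expect_error(auroc_pair(ps, pt, "x", "x"), "no negatives")
})

test_that("mean AUROC matrix is symmetric with unit diagonal", {
  pa <- make_random_pcm(30, c(k1 = 4, k2 = 4, k3 = 4), seed = 3, prefix = "a")
  pb <- make_random_pcm(30, c(m1 = 4, m2 = 4), seed = 4, prefix = "b")
  M <- mean_auroc_matrix(pa, pb)
  expect_identical(dim(M), c(5L, 5L))
  expect_equal(unclass(M), t(unclass(M)))
  expect_equal(unname(diag(M)), rep(1, 5))
  expect_true(all(M >= 0 & M <= 1))
})

test_that("independent random data scores near chance", {
  pa <- make_random_pcm(40, c(k1 = 20, k2 = 20), seed = 11, prefix = "a")
  pb <- make_random_pcm(40, c(m1 = 20, m2 = 20), seed = 12, prefix = "b")
  M <- mean_auroc_matrix(pa, pb)
  blk <- auroc_between_block(M, "A", "B")
  expect_lt(abs(mean(blk) - 0.5), 0.05)
})

test_that("permuting target cluster labels permutes AUROC columns", {
  pa <- make_random_pcm(30, c(k1 = 5, k2 = 5), seed = 21, prefix = "a")
  pb <- make_random_pcm(30, c(m1 = 5, m2 = 5, m3 = 5), seed = 22,
                        prefix = "b")
  M1 <- mean_auroc_matrix(pa, pb)
  # rename clusters of b: m1 -> m3, m2 -> m1, m3 -> m2
  pb2 <- pb
  pb2$cluster <- setNames(c(m1 = "m3", m2 = "m1", m3 = "m2")[pb$cluster],
                          names(pb$cluster))
  M2 <- mean_auroc_matrix(pa, pb2)
  expect_equal(unclass(M2)[paste0("A:", c("k1", "k2")), "B:m3"],
               unclass(M1)[paste0("A:", c("k1", "k2")), "B:m1"])
})

test_that("matched cluster programs give high AUROC and a family-wise tree", {
  set.seed(30)
  progs <- matrix(rnorm(50 * 2, sd = 2), ncol = 2)   # two program families
  build <- function(prefix, seed) {
    set.seed(seed)
    sizes <- c(f1a = 6, f1b = 6, f2a = 6)
    fam <- c(1, 1, 2)
    z <- do.call(cbind, lapply(seq_along(sizes), function(i)
      progs[, fam[i]] + matrix(rnorm(50 * sizes[i], sd = 0.6), nrow = 50)))
    ids <- sprintf("%s_pc%03d", prefix, seq_len(ncol(z)))
    dimnames(z) <- list(sprintf("g%03d", 1:50), ids)
    z <- t(scale(t(z))) * sqrt(ncol(z) / (ncol(z) - 1))
    structure(list(z = z,
                   cluster = setNames(rep(names(sizes), sizes), ids),
                   members = setNames(as.list(paste0(prefix, ids)), ids),
                   stage = "z"),
              class = "pseudo_cells")
  }
  pa <- build("a", 31); pb <- build("b", 32)
  M <- mean_auroc_matrix(pa, pb)
  tree <- auroc_dendrogram(M)
  # the two f2a clusters (one per dataset) are siblings: families beat datasets
  mrca <- ape::getMRCA(tree, c("A:f2a", "B:f2a"))
  clade <- ape::extract.clade(tree, mrca)
  expect_setequal(clade$tip.label, c("A:f2a", "B:f2a"))
  blk <- auroc_between_block(M, "A", "B")
  expect_gt(blk["f2a", "f2a"], 0.9)
})

test_that("auroc_dendrogram merges perfect matches first and ignores row order", {
  M <- matrix(c(1, 1, 0.2, 1, 1, 0.25, 0.2, 0.25, 1), nrow = 3,
              dimnames = list(c("A:k1", "B:k1", "B:k2"),
                              c("A:k1", "B:k1", "B:k2")))
  t1 <- auroc_dendrogram(M)
  clade <- ape::extract.clade(t1, ape::getMRCA(t1, c("A:k1", "B:k1")))
  expect_setequal(clade$tip.label, c("A:k1", "B:k1"))
  perm <- c(3, 1, 2)
  t2 <- auroc_dendrogram(M[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1], 0)
  expect_error(auroc_dendrogram(M[, 1:2]), "square")
})

test_that("correspondence edges follow the 0.80 / 0.05 rules strictly", {
  blk <- rbind(c1 = c(B1 = 0.95, B2 = 0.92, B3 = 0.70),
               c2 = c(B1 = 0.95, B2 = 0.85, B3 = 0.10),
               c3 = c(B1 = 0.70, B2 = 0.65, B3 = 0.80))
  net <- correspondence_network(blk)
  e1 <- net[net$source == "c1", ]
  expect_setequal(e1$target, c("B1", "B2"))
  expect_identical(e1$rank[e1$target == "B2"], "second")
  e2 <- net[net$source == "c2", ]
  expect_identical(e2$target, "B1")              # gap 0.10 >= 0.05: no second
  expect_false("c3" %in% net$source)             # all scores <= 0.80
})
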