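# Cluster-level expression summaries, marker/DEG detection, and
# correlation-distance dendrograms.
#
# The cluster summary averages, over the member nuclei, the within-cell UMI
# fraction of each gene and scales by 1e6 (a CPM-like quantity; equal to
# 100 x mean CP10K). Marker and DEG calling use the Wilcoxon rank-sum test
# with a normal approximation, tie correction and continuity correction;
# MAST-style hurdle modelling is deliberately out of scope and only the
# decision gates (FDR, fold change, percent expressed) are reproduced.

#' Per-cluster expression summary
#'
#' For each cluster and gene, the value is
#' `mean over member cells of (gene UMIs / cell total UMIs) * 1e6`.
#' The within-cell UMI share is treated as a fraction in \[0, 1\]; using a
#' 0-100 percentage would only rescale all values by 100 and cannot change
#' any downstream correlation or ranking.
#'
#' @param x a `SingleCellExperiment` UMI matrix.
#' @param labels per-cell cluster labels (defaults to the `cluster` metadata
#'   column). Every cell must be labelled and have total UMIs > 0.
#' @return object of class `cluster_expression`: list with `values`
#'   (clusters x genes dense matrix) and `n_cells` (named integer).
#' @export
cluster_expression <- function(x, labels = NULL) {
  m <- .counts(x)
  if (is.null(labels)) labels <- .coldata(x, "cluster")
  .assert(length(labels) == ncol(m), "one label per cell required")
  .assert(!anyNA(labels), "cluster_expression: unlabelled cells")
  totals <- Matrix::colSums(m)
  .assert(all(totals > 0), "cluster_expression: cells with zero total UMIs")
  cl <- sort(unique(labels))
  .assert(all(table(factor(labels, levels = cl)) > 0),
          "cluster_expression: empty cluster")
  frac <- m %*% Matrix::Diagonal(x = 1 / totals)   # per-cell UMI fractions
  ind <- Matrix::sparseMatrix(i = seq_along(labels),
                              j = match(labels, cl),
                              x = 1, dims = c(length(labels), length(cl)))
  n_cells <- Matrix::colSums(ind)
  vals <- t(as.matrix(frac %*% ind)) / n_cells * 1e6
  dimnames(vals) <- list(cl, rownames(m))
  structure(list(values = vals,
                 n_cells = setNames(as.integer(n_cells), cl)),
            class = "cluster_expression")
}

# Vectorized two-sided Wilcoxon rank-sum test (normal approximation with tie
# and continuity corrections) for each row of `mat`, group A vs the rest.
#' @noRd
.ranksum_p <- function(mat, in_a) {
  mat <- as.matrix(mat)
  n <- ncol(mat); n1 <- sum(in_a); n2 <- n - n1
  stopifnot(n1 > 0L, n2 > 0L)
  p <- numeric(nrow(mat))
  for (g in seq_len(nrow(mat))) {
    r <- rank(mat[g, ])
    w <- sum(r[in_a])
    mu <- n1 * (n + 1) / 2
    ties <- table(mat[g, ])
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) { p[g] <- 1; next }
    z <- (abs(w - mu) - 0.5) / sqrt(sig2)   # continuity correction
    p[g] <- min(1, 2 * pnorm(-max(z, 0)))
  }
  p
}

#' One-vs-rest marker detection
#'
#' For each cluster, genes are pre-filtered by expression fraction
#' (`>= min_pct` of member cells with UMI >= 1) and natural-log fold change
#' of mean CP10K + 1 (`>= min_logfc`; only positive markers when
#' `positive_only`), then tested with the two-sided Wilcoxon rank-sum test of
#' the cluster against all other cells on CP10K values. P values are
#' Benjamini-Hochberg adjusted across the genes tested within each cluster.
#'
#' @param x a `SingleCellExperiment` UMI matrix.
#' @param labels per-cell cluster labels (default: `cluster` metadata).
#' @param min_pct minimum expressing fraction in the cluster (default 0.25).
#' @param min_logfc minimum natural-log fold change (default 0.25).
#' @param positive_only keep only up-regulated genes (default TRUE).
#' @return data.frame with columns `cluster`, `gene`, `avg_logfc` (natural
#'   log), `pct_in`, `pct_out`, `p_value`, `fdr`. Clusters with fewer than 3
#'   cells are skipped with a warning.
#' @export
find_markers <- function(x, labels = NULL, min_pct = 0.25,
                         min_logfc = 0.25, positive_only = TRUE) {
  m <- .counts(x)
  if (is.null(labels)) labels <- .coldata(x, "cluster")
  cl <- sort(unique(labels))
  .assert(length(cl) >= 2L, "find_markers: need >= 2 clusters")
  norm <- cp10k(m)
  out <- list()
  for (k in cl) {
    in_k <- labels == k
    if (sum(in_k) < 3L) {
      warning(sprintf("find_markers: cluster '%s' has < 3 cells; skipped", k))
      next
    }
    pct_in <- Matrix::rowSums(m[, in_k, drop = FALSE] >= 1) / sum(in_k)
    pct_out <- Matrix::rowSums(m[, !in_k, drop = FALSE] >= 1) / sum(!in_k)
    mu_in <- Matrix::rowSums(norm[, in_k, drop = FALSE]) / sum(in_k)
    mu_out <- Matrix::rowSums(norm[, !in_k, drop = FALSE]) / sum(!in_k)
    lfc <- log(mu_in + 1) - log(mu_out + 1)
    test <- pct_in >= min_pct &
      (if (positive_only) lfc >= min_logfc else abs(lfc) >= min_logfc)
    if (!any(test)) next
    p <- .ranksum_p(norm[test, , drop = FALSE], in_k)
    out[[k]] <- data.frame(cluster = k, gene = rownames(m)[test],
                           avg_logfc = lfc[test], pct_in = pct_in[test],
                           pct_out = pct_out[test], p_value = p,
                           fdr = .bh(p), row.names = NULL)
  }
  if (!length(out))
    return(data.frame(cluster = character(0), gene = character(0),
                      avg_logfc = numeric(0), pct_in = numeric(0),
                      pct_out = numeric(0), p_value = numeric(0),
                      fdr = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$cluster, res$fdr, res$p_value), ]
}

#' Differential expression between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test per gene on CP10K values, with the
#' significance gates `fdr < fdr_cut`, `fold_change > min_fold` and
#' `pct_expressing > min_pct` (fraction of up-group cells with UMI >= 1).
#' Fold change is the ratio of group mean CP10K with a 1e-9 pseudo-count,
#' oriented so that `fold_change >= 1` and `up_group` names the higher group.
#'
#' @param x a `SingleCellExperiment` UMI matrix.
#' @param labels per-cell group labels (default: `cluster` metadata).
#' @param group_a,group_b label values (possibly several) defining the two
#'   groups; they must not select identical cell sets.
#' @param fdr_cut,min_fold,min_pct the gates (defaults 0.05, 1.25, 0.20).
#' @return data.frame with one row per gene: `gene`, `up_group`,
#'   `fold_change`, `pct_expressing`, `p_value`, `fdr`, `significant`.
#' @export
find_degs <- function(x, labels = NULL, group_a, group_b,
                      fdr_cut = 0.05, min_fold = 1.25, min_pct = 0.20) {
  m <- .counts(x)
  if (is.null(labels)) labels <- .coldata(x, "cluster")
  in_a <- labels %in% group_a
  in_b <- labels %in% group_b
  .assert(any(in_a) && any(in_b), "find_degs: empty group")
  .assert(!identical(which(in_a), which(in_b)),
          "find_degs: the two groups select identical cells")
  .assert(!any(in_a & in_b), "find_degs: groups overlap")
  keep <- in_a | in_b
  norm <- cp10k(m[, keep, drop = FALSE])
  a <- in_a[keep]
  mu_a <- Matrix::rowSums(norm[, a, drop = FALSE]) / sum(a)
  mu_b <- Matrix::rowSums(norm[, !a, drop = FALSE]) / sum(!a)
  up_is_a <- mu_a >= mu_b
  eps <- 1e-9
  fold <- ifelse(up_is_a, (mu_a + eps) / (mu_b + eps),
                 (mu_b + eps) / (mu_a + eps))
  pct_a <- Matrix::rowSums(m[, keep, drop = FALSE][, a, drop = FALSE] >= 1) / sum(a)
  pct_b <- Matrix::rowSums(m[, keep, drop = FALSE][, !a, drop = FALSE] >= 1) / sum(!a)
  pct_up <- ifelse(up_is_a, pct_a, pct_b)
  p <- .ranksum_p(norm, a)
  fdr <- .bh(p)
  data.frame(gene = rownames(m),
             up_group = ifelse(up_is_a, paste(group_a, collapse = "+"),
                               paste(group_b, collapse = "+")),
             fold_change = fold, pct_expressing = pct_up,
             p_value = p, fdr = fdr,
             significant = fdr < fdr_cut & fold > min_fold &
               pct_up > min_pct,
             row.names = NULL)
}

#' Correlation-distance Ward dendrogram of cluster expression profiles
#'
#' Ranks genes by mean expression across the clusters (ties broken by gene
#' identifier), keeps the top `top_n_genes`, computes the distance
#' `1 - Pearson correlation` between cluster profiles and agglomerates with
#' classic Ward linkage (`"ward.D"`). Branch support is the plain bootstrap
#' proportion: the fraction of gene-resampling replicates whose tree contains
#' each internal clade.
#'
#' @param expr a [cluster_expression()] object.
#' @param top_n_genes genes to keep (default 8,000; capped at the gene count
#'   with a warning).
#' @param bootstrap_reps bootstrap replicates (default 100; 0 disables).
#' @param seed seed for the gene resampling.
#' @return list with `tree` (an [ape::phylo] whose node labels carry the
#'   support fractions), `support` (numeric per internal node), `genes_used`.
#' @export
correlation_dendrogram <- function(expr, top_n_genes = 8000L,
                                   bootstrap_reps = 100L, seed = 1L) {
  .assert(inherits(expr, "cluster_expression"),
          "expr must come from cluster_expression()")
  vals <- expr$values
  .assert(nrow(vals) >= 2L, "need >= 2 clusters")
  if (top_n_genes > ncol(vals)) {
    warning(sprintf("top_n_genes = %d exceeds the %d genes available; using all",
                    top_n_genes, ncol(vals)))
    top_n_genes <- ncol(vals)
  }
  means <- colMeans(vals)
  ord <- order(-means, colnames(vals))   # ties broken by gene id
  genes <- colnames(vals)[ord[seq_len(top_n_genes)]]
  sub <- vals[, genes, drop = FALSE]

  .tree_of <- function(mat) {
    d <- as.dist(1 - cor(t(mat)))
    ape::as.phylo(hclust(d, method = "ward.D"))
  }
  main <- .tree_of(sub)
  support <- NULL
  if (bootstrap_reps > 0L && nrow(vals) >= 3L) {
    set.seed(seed)
    boots <- replicate(bootstrap_reps, {
      gs <- sample.int(ncol(sub), replace = TRUE)
      .tree_of(sub[, gs, drop = FALSE])
    }, simplify = FALSE)
    counts <- ape::prop.clades(main, boots, rooted = TRUE)
    counts[is.na(counts)] <- 0L
    support <- counts / bootstrap_reps
    main$node.label <- formatC(support, format = "f", digits = 2)
  }
  list(tree = main, support = support, genes_used = genes)
}
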