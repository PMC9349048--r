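# Pseudo-cell construction and neighbour-voting mean-AUROC correspondence of
# cell clusters within and between datasets.
#
# A pseudo-cell merges the UMI counts of `group_size` cells picked at random
# without replacement within one cluster; the sums are CP10K-normalized and,
# on a chosen gene subset (orthologous genes that are markers in at least one
# of the two compared datasets), z-transformed per gene with the population
# standard deviation. A target pseudo-cell's vote for a source cluster is its
# mean Pearson correlation with that cluster's pseudo-cells; the AUROC is the
# Mann-Whitney probability (ties counted 1/2) that a member of the candidate
# cluster out-votes a non-member. Because AUROC is invariant under strictly
# monotone transforms of the votes, rank-normalizing the votes would be a
# no-op and is not done.

#' Build pseudo-cells by random disjoint grouping within clusters
#'
#' Within each cluster, cells are shuffled (seeded) and partitioned into
#' disjoint groups of exactly `group_size`; remainder cells are dropped and
#' counted. Per group, UMI counts are summed by gene and CP10K-normalized.
#'
#' @param x a `SingleCellExperiment` UMI matrix.
#' @param labels per-cell cluster labels (default: `cluster` metadata).
#' @param group_size cells per pseudo-cell (default 10, must be >= 2).
#' @param seed seed for the within-cluster shuffles.
#' @return object of class `pseudo_cells`: list with `counts` (genes x
#'   pseudo-cells raw sums), `cp10k` (same shape), `cluster` (per
#'   pseudo-cell), `members` (list of member cell ids), `dropped` (named
#'   count of remainder cells per cluster), `stage = "cp10k"`.
#' @export
make_pseudocells <- function(x, labels = NULL, group_size = 10L, seed = 1L) {
  m <- .counts(x)
  if (is.null(labels)) labels <- .coldata(x, "cluster")
  .assert(group_size >= 2L, "group_size must be >= 2")
  set.seed(seed)
  cl <- sort(unique(labels))
  assign_members <- list(); assign_cluster <- character(0)
  dropped <- setNames(integer(length(cl)), cl)
  for (k in cl) {
    cells <- colnames(m)[labels == k]
    n_groups <- length(cells) %/% group_size
    dropped[k] <- length(cells) - n_groups * group_size
    if (n_groups == 0L) {
      warning(sprintf(
        "make_pseudocells: cluster '%s' has %d < %d cells; no pseudo-cells",
        k, length(cells), group_size))
      next
    }
    shuffled <- sample(cells)
    for (gi in seq_len(n_groups)) {
      assign_members <- c(assign_members,
                          list(shuffled[((gi - 1L) * group_size + 1L):(gi * group_size)]))
      assign_cluster <- c(assign_cluster, k)
    }
  }
  .assert(length(assign_members) > 0L,
          "make_pseudocells: no cluster yielded any pseudo-cell")
  ids <- sprintf("pc%04d_%s", seq_along(assign_members), assign_cluster)
  ind <- Matrix::sparseMatrix(
    i = match(unlist(assign_members), colnames(m)),
    j = rep(seq_along(assign_members), each = group_size),
    x = 1, dims = c(ncol(m), length(assign_members)))
  counts <- m %*% ind
  dimnames(counts) <- list(rownames(m), ids)
  structure(list(counts = counts, cp10k = cp10k(counts),
                 cluster = setNames(assign_cluster, ids),
                 members = setNames(assign_members, ids),
                 dropped = dropped, stage = "cp10k"),
            class = "pseudo_cells")
}

#' Z-transform pseudo-cell expression on a gene subset
#'
#' Restricts the CP10K pseudo-cell matrix to `gene_subset` and standardizes
#' each gene as `z = (x - m) / s.d.` across all pseudo-cells of the dataset,
#' with the population (divide-by-n) standard deviation. Genes with zero
#' variance are set to z = 0.
#'
#' @param pcm a [make_pseudocells()] object with >= 2 pseudo-cells.
#' @param gene_subset non-empty character vector of gene ids; typically the
#'   orthologous genes that are cluster markers in at least one of the two
#'   compared datasets.
#' @return the `pseudo_cells` object with an added dense matrix `z`
#'   (subset genes x pseudo-cells), `z_mean`, `z_sd`, and `stage = "z"`.
#' @export
standardize_pseudocells <- function(pcm, gene_subset) {
  .assert(inherits(pcm, "pseudo_cells"), "pcm must come from make_pseudocells()")
  .assert(length(gene_subset) > 0L, "standardize_pseudocells: empty gene subset")
  .assert(ncol(pcm$cp10k) >= 2L, "need >= 2 pseudo-cells to standardize")
  .assert(all(gene_subset %in% rownames(pcm$cp10k)),
          "gene subset contains unknown genes")
  xm <- as.matrix(pcm$cp10k[gene_subset, , drop = FALSE])
  mu <- rowMeans(xm)
  n <- ncol(xm)
  sdev <- sqrt(rowSums((xm - mu)^2) / n)   # population s.d.
  z <- (xm - mu) / ifelse(sdev > 0, sdev, 1)
  z[sdev == 0, ] <- 0
  pcm$z <- z
  pcm$z_mean <- mu
  pcm$z_sd <- sdev
  pcm$stage <- "z"
  pcm
}

# AUROC from votes via midranks: (R_pos - n_pos(n_pos+1)/2) / (n_pos n_neg).
#' @noRd
.auroc_from_votes <- function(votes, is_pos) {
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  stopifnot(n_pos > 0L, n_neg > 0L)
  r <- rank(votes)   # midranks handle ties as 1/2
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Votes of every target pseudo-cell for a source cluster: mean Pearson
# correlation with the source cluster's pseudo-cells. When source and target
# are the same dataset, each member's correlation with itself is excluded
# from its own vote.
#' @noRd
.votes_for <- function(source_pcm, target_pcm, source_cluster) {
  .assert(!is.null(source_pcm$z) && !is.null(target_pcm$z),
          "pseudo-cells must be standardized first (stage 'z')")
  .assert(identical(rownames(source_pcm$z), rownames(target_pcm$z)),
          "source and target must share the standardized gene subset")
  src <- source_pcm$cluster == source_cluster
  .assert(any(src), "unknown source cluster '%s'", source_cluster)
  cc <- suppressWarnings(cor(target_pcm$z, source_pcm$z[, src, drop = FALSE]))
  cc[is.na(cc)] <- 0   # zero-variance pseudo-cell profiles
  # same dataset? (member cell ids are globally unique across datasets)
  same <- identical(source_pcm$members, target_pcm$members)
  if (!same) return(rowMeans(cc))
  n_src <- sum(src)
  self <- match(colnames(target_pcm$z), colnames(source_pcm$z)[src])
  is_member <- !is.na(self)
  .assert(n_src > 1L || !any(is_member),
          "within-dataset vote for a singleton cluster is undefined")
  votes <- rowSums(cc)
  self_cor <- rep(0, length(votes))
  self_cor[is_member] <- cc[cbind(which(is_member), self[is_member])]
  votes[is_member] <- (votes[is_member] - self_cor[is_member]) / (n_src - 1)
  votes[!is_member] <- votes[!is_member] / n_src
  votes
}

#' Neighbour-voting AUROC for one cluster pair
#'
#' Votes every pseudo-cell of the target dataset for `source_cluster` (mean
#' Pearson correlation with that cluster's source pseudo-cells), then scores
#' how well the votes rank `target_cluster` members above non-members:
#' the Mann-Whitney AUROC with ties counted one half.
#'
#' @param source_pcm,target_pcm standardized [pseudo_cells] objects sharing
#'   the gene subset (pass the same object twice for within-dataset scores;
#'   self-correlations are then excluded from member votes).
#' @param source_cluster cluster voting from the source dataset.
#' @param target_cluster candidate cluster in the target dataset; the target
#'   dataset must also contain non-members.
#' @return AUROC in \[0, 1\].
#' @export
auroc_pair <- function(source_pcm, target_pcm, source_cluster,
                       target_cluster) {
  votes <- .votes_for(source_pcm, target_pcm, source_cluster)
  is_pos <- target_pcm$cluster == target_cluster
  .assert(any(is_pos), "unknown target cluster '%s'", target_cluster)
  .assert(any(!is_pos),
          "auroc_pair: target dataset has only the target cluster (no negatives)")
  .auroc_from_votes(votes, is_pos)
}

#' Mean-AUROC matrix over all cluster pairs of two datasets
#'
#' Between-dataset entries average the two voting directions:
#' `(AUROC a->b + AUROC b->a) / 2`. Within-dataset entries are computed the
#' same way inside one dataset, with self-correlations excluded from member
#' votes. The diagonal is defined as 1.
#'
#' @param pcm_a,pcm_b standardized [pseudo_cells] objects sharing the gene
#'   subset.
#' @param labels_a,labels_b dataset labels used to prefix cluster names
#'   (default `"A"`, `"B"`).
#' @return symmetric matrix of class `auroc_matrix` over
#'   `<dataset>:<cluster>` rows/columns, entries in \[0, 1\].
#' @export
mean_auroc_matrix <- function(pcm_a, pcm_b, labels_a = "A", labels_b = "B") {
  cl_a <- sort(unique(pcm_a$cluster))
  cl_b <- sort(unique(pcm_b$cluster))
  all_ids <- c(paste0(labels_a, ":", cl_a), paste0(labels_b, ":", cl_b))
  n <- length(all_ids)
  M <- matrix(NA_real_, n, n, dimnames = list(all_ids, all_ids))
  diag(M) <- 1

  # cache votes: by (source dataset, source cluster, target dataset)
  .block <- function(pcm_s, pcm_t, cl_s, cl_t, off_s, off_t) {
    for (i in seq_along(cl_s)) {
      votes <- .votes_for(pcm_s, pcm_t, cl_s[i])
      for (j in seq_along(cl_t)) {
        if (off_s == off_t && i == j) next
        is_pos <- pcm_t$cluster == cl_t[j]
        if (!any(!is_pos)) stop("auroc undefined: no negatives")
        a <- .auroc_from_votes(votes, is_pos)
        ii <- off_s + i; jj <- off_t + j
        M[jj, ii] <<- if (is.na(M[jj, ii])) a else (M[jj, ii] + a) / 2
        M[ii, jj] <<- M[jj, ii]
      }
    }
  }
  # within A and within B: both directions inside one dataset
  .block(pcm_a, pcm_a, cl_a, cl_a, 0L, 0L)
  .block(pcm_b, pcm_b, cl_b, cl_b, length(cl_a), length(cl_a))
  # between: a -> b and b -> a, averaged into the same symmetric entries
  .block(pcm_a, pcm_b, cl_a, cl_b, 0L, length(cl_a))
  .block(pcm_b, pcm_a, cl_b, cl_a, length(cl_a), 0L)
  structure(M, class = c("auroc_matrix", "matrix"),
            datasets = c(labels_a, labels_b))
}

#' Ward dendrogram on 1 - AUROC distances
#'
#' @param auroc a square [mean_auroc_matrix()] result (or any symmetric
#'   cluster x cluster AUROC matrix).
#' @return an [ape::phylo] tree with leaves `dataset:cluster`.
#' @export
auroc_dendrogram <- function(auroc) {
  .assert(nrow(auroc) == ncol(auroc) && nrow(auroc) >= 2L,
          "auroc_dendrogram: need a square matrix of >= 2 clusters")
  d <- pmax(1 - unclass(auroc), 0)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  ape::as.phylo(hclust(as.dist(d), method = "ward.D"))
}

#' Cross-dataset correspondence edges from an AUROC block
#'
#' Per source cluster: an edge to its top-scoring target cluster when that
#' AUROC exceeds `min_auroc` (strict), plus a second edge when the runner-up
#' also exceeds `min_auroc` and trails the top hit by less than
#' `second_hit_gap` (strict inequalities on both sides).
#'
#' @param between matrix of AUROC scores with source clusters as rows and
#'   target clusters as columns (e.g. the between-dataset block of a
#'   [mean_auroc_matrix()]).
#' @param min_auroc minimum score for any edge (default 0.80).
#' @param second_hit_gap maximum top-minus-second gap for a second edge
#'   (default 0.05).
#' @return data.frame with columns `source`, `target`, `auroc`,
#'   `rank` (`"top"` or `"second"`); clusters may contribute zero edges.
#' @export
correspondence_network <- function(between, min_auroc = 0.80,
                                   second_hit_gap = 0.05) {
  .assert(ncol(between) >= 1L, "no target clusters")
  out <- list()
  for (i in seq_len(nrow(between))) {
    sc <- rownames(between)[i] %||% as.character(i)
    v <- between[i, ]
    ord <- order(-v, colnames(between))
    top <- ord[1]
    if (v[top] > min_auroc) {
      out[[length(out) + 1L]] <- data.frame(
        source = sc, target = colnames(between)[top],
        auroc = unname(v[top]), rank = "top")
      if (length(ord) >= 2L) {
        second <- ord[2]
        if (v[second] > min_auroc && (v[top] - v[second]) < second_hit_gap)
          out[[length(out) + 1L]] <- data.frame(
            source = sc, target = colnames(between)[second],
            auroc = unname(v[second]), rank = "second")
      }
    }
  }
  if (!length(out))
    return(data.frame(source = character(0), target = character(0),
                      auroc = numeric(0), rank = character(0)))
  do.call(rbind, out)
}

#' Extract the between-dataset block of an AUROC matrix
#'
#' @param auroc a [mean_auroc_matrix()] result.
#' @param source_dataset,target_dataset dataset labels as used in the row
#'   names (`dataset:cluster`).
#' @return matrix with source clusters as rows, target clusters as columns;
#'   dimnames keep the bare cluster names.
#' @export
auroc_between_block <- function(auroc, source_dataset, target_dataset) {
  rn <- rownames(auroc)
  src <- startsWith(rn, paste0(source_dataset, ":"))
  tgt <- startsWith(rn, paste0(target_dataset, ":"))
  .assert(any(src) && any(tgt), "dataset label not found in AUROC matrix")
  blk <- unclass(auroc)[src, tgt, drop = FALSE]
  rownames(blk) <- sub("^[^:]*:", "", rownames(blk))
  colnames(blk) <- sub("^[^:]*:", "", colnames(blk))
  blk
}

#' Write a correspondence network as edge-list TSV and GraphML
#'
#' @param edges data.frame from [correspondence_network()].
#' @param tsv_path,graphml_path output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_network <- function(edges, tsv_path = NULL, graphml_path = NULL) {
  if (!is.null(tsv_path)) .write_tsv(edges, tsv_path)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(c(tsv = tsv_path, graphml = graphml_path))
}
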