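# Shared fixture builders. Everything is generated in code; no binary files.

# Dense counts -> SingleCellExperiment with optional cluster labels.
tiny_sce <- function(counts, cluster = NULL, phenotype = NULL) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("cell%03d", seq_len(ncol(counts)))
  meta <- data.frame(row.names = colnames(counts))
  if (!is.null(cluster)) meta$cluster <- cluster
  if (!is.null(phenotype)) meta$phenotype <- phenotype
  umi_matrix(counts, meta)
}

# Small two-species atlas used by several files (one shot per file).
small_atlas <- function(seed = 101, n_clusters = 4L, n_genes = 300L,
                        cells_per_replicate = 250L, n_species = 2L,
                        phenotypes = c(ctrl = 2L, case = 2L), ...) {
  simulate_atlas(atlas_sim_config(
    n_species = n_species, n_clusters = n_clusters, n_genes = n_genes,
    n_marker_genes_per_cluster = 8L, marker_fold = 8,
    phenotypes = phenotypes, cells_per_replicate = cells_per_replicate,
    mean_umi_per_cell = 600, seed = seed, ...))
}

# Hand-built SAM line (flag 0, MAPQ 255) for the filter tests.
sam_record <- function(id, chrom, pos, cigar, nh = 1L, seq = NULL) {
  len <- sum(as.integer(
    regmatches(cigar, gregexpr("\\d+(?=[MIS=X])", cigar, perl = TRUE))[[1]]))
  if (is.null(seq)) seq <- strrep("A", len)
  paste(id, 0L, chrom, pos, 255L, cigar, "*", 0L, 0L, seq,
        strrep("I", nchar(seq)), sprintf("NH:i:%d", nh), sep = "\t")
}

sam_header <- function(genome) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome), Biostrings::width(genome)))
}

# Genome with planted junction motifs: list of chrom -> character string.
toy_genome <- function(lengths, plants = list()) {
  set.seed(99)
  seqs <- vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  for (p in plants) {   # p = list(chrom, pos, motif)
    substr(seqs[[p[[1]]]], p[[2]], p[[2]] + nchar(p[[3]]) - 1L) <- p[[3]]
  }
  Biostrings::DNAStringSet(seqs)
}

# Independent two-sided rank-sum p by exhaustive permutation (small n).
perm_ranksum_p <- function(x, in_a) {
  n <- length(x); idx_a <- which(in_a)
  r <- rank(x)
  obs <- abs(sum(r[idx_a]) - sum(in_a) * (n + 1) / 2)
  combs <- utils::combn(n, length(idx_a))
  devs <- apply(combs, 2, function(ix)
    abs(sum(r[ix]) - length(ix) * (n + 1) / 2))
  mean(devs >= obs - 1e-12)
}

# Independent two-sided Fisher p: enumerate margin-fixed tables with
# lchoose-based probabilities.
enum_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  xs <- max(0, k - n):min(k, m)
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  pr <- exp(logp)
  pobs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# Brute-force AUROC oracle: votes by explicit per-pair correlation loop,
# then exhaustive (positive, negative) pair counting.
oracle_auroc <- function(source_pcm, target_pcm, source_cluster,
                         target_cluster) {
  src_ids <- names(source_pcm$cluster)[source_pcm$cluster == source_cluster]
  same <- identical(source_pcm$members, target_pcm$members)
  votes <- vapply(colnames(target_pcm$z), function(tc) {
    others <- setdiff(src_ids, if (same) tc else character(0))
    mean(vapply(others, function(sc)
      stats::cor(target_pcm$z[, tc], source_pcm$z[, sc]), numeric(1)))
  }, numeric(1))
  pos <- votes[target_pcm$cluster == target_cluster]
  neg <- votes[target_pcm$cluster != target_cluster]
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  wins / (length(pos) * length(neg))
}
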