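# Alignment-record filtering and nucleus-level QC.
#
# The read filter implements three bespoke post-alignment rules: drop reads
# reported at multiple genomic positions, drop spliced reads spanning any
# gap > 50 kb, and drop spliced reads whose intron terminal dinucleotides are
# not one of the canonical splice motifs (GT/AG, GC/AG, AT/AC) in either
# genomic orientation. Nucleus QC keeps cells with 200-2,000 expressed genes
# and at most 1% mitochondrial UMIs.

.CANONICAL_MOTIFS <- c("GTAG", "GCAG", "ATAC",   # forward orientation
                       "CTAC", "CTGC", "GTAT")   # reverse complement

#' Filter spliced alignment records against a genome
#'
#' Reads a SAM file (NH tag optional) and a genome, and applies, in order:
#' \enumerate{
#'   \item discard reads aligned to multiple positions (NH > 1, or the same
#'     read id occurring in more than one record);
#'   \item discard spliced reads with any alignment gap > `max_gap` bases;
#'   \item discard spliced reads with any intron whose donor/acceptor
#'     dinucleotides, checked on both genomic orientations, are not GT/AG,
#'     GC/AG or AT/AC.
#' }
#' Each discarded read is attributed to the first rule it fails.
#'
#' @param sam path to a SAM file, or a character vector of SAM lines
#'   (header included).
#' @param genome a [Biostrings::DNAStringSet] or path to a FASTA file. Must
#'   contain every chromosome referenced by a spliced record.
#' @param max_gap maximum tolerated gap (default 50,000 bases).
#' @return list with `pass` (read ids kept), `discard_counts` (named integer:
#'   multimapped / long_gap / noncanonical) and `n_reads`.
#' @export
filter_alignments <- function(sam, genome, max_gap = 50000L) {
  sam_path <- sam
  if (length(sam) > 1L || !file.exists(sam[1])) {
    sam_path <- tempfile(fileext = ".sam")
    on.exit(unlink(sam_path), add = TRUE)
    writeLines(sam, sam_path)
  }
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))

  bam <- Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  gal <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(
      what = "qname", tag = "NH",
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))
  qname <- S4Vectors::mcols(gal)$qname
  nh <- S4Vectors::mcols(gal)$NH
  nh[is.na(nh)] <- 1L

  multi_ids <- unique(c(qname[nh > 1L], qname[duplicated(qname)]))
  verdict <- setNames(rep("pass", length(unique(qname))), unique(qname))
  verdict[multi_ids] <- "multimapped"

  # flatten all introns once; per-intron work is then fully vectorized
  introns <- GenomicAlignments::junctions(gal)
  chr_str <- setNames(as.character(genome), names(genome))
  seqn <- as.character(GenomicAlignments::seqnames(gal))
  rec_of <- rep(seq_along(gal), lengths(introns))
  if (length(rec_of)) {
    flat <- unlist(introns, use.names = FALSE)
    chrom <- seqn[rec_of]
    bad_chrom <- !(chrom %in% names(chr_str))
    .assert(!any(bad_chrom),
            "filter_alignments: record '%s' is spliced on chromosome '%s' absent from the genome",
            qname[rec_of[which(bad_chrom)[1]]], chrom[which(bad_chrom)[1]])
    starts <- GenomicRanges::start(flat); ends <- GenomicRanges::end(flat)
    over <- ends > nchar(chr_str)[chrom]
    .assert(!any(over),
            "filter_alignments: gap of record '%s' extends past the end of '%s'",
            qname[rec_of[which(over)[1]]], chrom[which(over)[1]])
    long <- (ends - starts + 1L) > max_gap
    motifs <- paste0(substr(chr_str[chrom], starts, starts + 1L),
                     substr(chr_str[chrom], ends - 1L, ends))
    noncan <- !(motifs %in% .CANONICAL_MOTIFS)
    # record-level verdicts; rule order: length first, then motif
    id_long <- unique(qname[rec_of[long]])
    id_noncan <- setdiff(unique(qname[rec_of[noncan]]), id_long)
    sel <- verdict[id_long] == "pass"
    verdict[id_long[sel]] <- "long_gap"
    sel <- verdict[id_noncan] == "pass"
    verdict[id_noncan[sel]] <- "noncanonical"
  }

  list(pass = names(verdict)[verdict == "pass"],
       discard_counts = c(
         multimapped = sum(verdict == "multimapped"),
         long_gap = sum(verdict == "long_gap"),
         noncanonical = sum(verdict == "noncanonical")),
       n_reads = length(verdict))
}

#' Nucleus-level quality control
#'
#' Keeps nuclei with `min_genes <= n <= max_genes` expressed genes (a gene is
#' expressed when its UMI count is >= 1) and a mitochondrial UMI fraction of
#' at most `max_mito_frac`. Retained counts are never modified: QC subsets
#' only.
#'
#' @param x a `SingleCellExperiment` UMI matrix (see [umi_matrix()]).
#' @param mito_genes character vector of mitochondrial gene ids; must be a
#'   subset of `rownames(x)`.
#' @param min_genes,max_genes inclusive bounds on detected genes
#'   (defaults 200 and 2,000).
#' @param max_mito_frac maximum mitochondrial fraction (default 0.01).
#' @return list with `matrix` (the filtered object) and `report` (one row per
#'   input cell: `cell_id`, `n_genes_detected`, `total_umis`,
#'   `mito_fraction`, `pass`).
#' @export
qc_nuclei <- function(x, mito_genes, min_genes = 200L, max_genes = 2000L,
                      max_mito_frac = 0.01) {
  m <- .counts(x)
  .assert(ncol(m) > 0L && nrow(m) > 0L, "qc_nuclei: empty matrix")
  .assert(all(mito_genes %in% rownames(m)),
          "qc_nuclei: mito_genes must all be present in the matrix")
  n_genes <- Matrix::colSums(m >= 1)
  totals <- Matrix::colSums(m)
  mito <- if (length(mito_genes))
    Matrix::colSums(m[mito_genes, , drop = FALSE]) else rep(0, ncol(m))
  mito_frac <- ifelse(totals > 0, mito / totals, 0)
  pass <- n_genes >= min_genes & n_genes <= max_genes &
    mito_frac <= max_mito_frac
  report <- data.frame(cell_id = colnames(m),
                       n_genes_detected = as.integer(n_genes),
                       total_umis = as.integer(totals),
                       mito_fraction = as.numeric(mito_frac),
                       pass = pass, row.names = NULL)
  list(matrix = x[, pass, drop = FALSE], report = report)
}

#' Counts-per-10,000 normalization
#'
#' `value = count / cell_total * 10000`; every cell column of the result sums
#' to 10,000 up to float error. Cells with zero total UMIs are an error: QC
#' first.
#'
#' @param x a `SingleCellExperiment` or a genes x cells count matrix.
#' @return sparse genes x cells matrix of CP10K values.
#' @export
cp10k <- function(x) {
  m <- .counts(x)
  totals <- Matrix::colSums(m)
  .assert(all(totals > 0),
          "cp10k: %d cell(s) have zero total UMIs; run QC first",
          sum(totals == 0))
  res <- m %*% Matrix::Diagonal(x = 1e4 / totals)
  dimnames(res) <- dimnames(m)
  res
}

#' Correlate phenotype-pooled snRNA-seq pseudo-bulk with bulk RNA-seq
#'
#' Pools UMI counts by gene within each phenotype, pools the bulk counts the
#' same way, converts both pools to CP10K, removes genes with CP10K < 1 in
#' both datasets, and reports the Pearson correlation of log2(CP10K + 1)
#' values per phenotype.
#'
#' @param x a `SingleCellExperiment` with a `phenotype` column in its cell
#'   metadata (or `phenotype` supplied explicitly).
#' @param bulk_counts genes x samples matrix of bulk read counts sharing the
#'   gene namespace of `x`.
#' @param bulk_phenotype phenotype label per bulk sample (defaults to the
#'   column names of `bulk_counts`).
#' @param phenotype optional per-cell phenotype labels overriding metadata.
#' @return data.frame with one row per phenotype: `phenotype`, `r`,
#'   `n_genes` used.
#' @export
pseudobulk_correlation <- function(x, bulk_counts, bulk_phenotype = NULL,
                                   phenotype = NULL) {
  m <- .counts(x)
  if (is.null(phenotype)) phenotype <- .coldata(x, "phenotype")
  bulk_counts <- as.matrix(bulk_counts)
  if (is.null(bulk_phenotype)) bulk_phenotype <- colnames(bulk_counts)
  shared <- intersect(rownames(m), rownames(bulk_counts))
  .assert(length(shared) >= 3L,
          "pseudobulk_correlation: fewer than 3 shared genes")
  phenos <- intersect(unique(phenotype), unique(bulk_phenotype))
  .assert(length(phenos) > 0L, "no phenotype shared between datasets")
  out <- lapply(phenos, function(ph) {
    sn <- Matrix::rowSums(m[shared, phenotype == ph, drop = FALSE])
    bk <- rowSums(bulk_counts[shared, bulk_phenotype == ph, drop = FALSE])
    sn10 <- sn / sum(sn) * 1e4
    bk10 <- bk / sum(bk) * 1e4
    keep <- !(sn10 < 1 & bk10 < 1)
    .assert(sum(keep) >= 3L,
            "pseudobulk_correlation: fewer than 3 genes survive the CP10K >= 1 filter for '%s'",
            ph)
    data.frame(phenotype = ph,
               r = cor(log2(sn10[keep] + 1), log2(bk10[keep] + 1)),
               n_genes = sum(keep))
  })
  do.call(rbind, out)
}
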