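# Toy spliced-alignment generator for exercising the read filter.
#
# Reads fall into four classes: multi-mapped (NH > 1), spliced across a long
# (> 50 kb) gap, spliced with a non-canonical intron motif, and good reads
# (unspliced, or spliced with a canonical GT/AG-family motif in either
# genomic orientation). The genome sequence carries the planted donor and
# acceptor dinucleotides at every junction, so the filter has to read them
# back from the FASTA rather than trust the read class.

#' Simulate SAM records and a matching genome for the alignment filter
#'
#' @param n_reads total number of reads to emit.
#' @param frac_multimapped fraction of reads reported with alignment
#'   multiplicity `NH = 2`.
#' @param frac_long_gap fraction of spliced reads spanning a 60 kb gap
#'   (fails the > 50 kb rule; motifs are kept canonical so the length rule
#'   alone rejects them).
#' @param frac_noncanonical fraction of spliced reads whose junction motif is
#'   AA/AA (non-canonical under both orientations).
#' @param seed integer seed; output is byte-identical for a fixed seed.
#' @param gap_long gap length for the long-gap class (default 60,000).
#' @param gap_short intron length for normally spliced reads (default 1,000).
#' @return list with `sam` (character vector of header + alignment lines),
#'   `genome` (a [Biostrings::DNAStringSet]), `expected_pass` (read ids the
#'   filter must keep) and `reads` (data.frame read_id/class).
#' @export
simulate_sam <- function(n_reads,
                         frac_multimapped = 0.1,
                         frac_long_gap = 0.1,
                         frac_noncanonical = 0.1,
                         seed = 1L,
                         gap_long = 60000L,
                         gap_short = 1000L) {
  .assert(n_reads >= 1, "n_reads must be >= 1")
  fracs <- c(frac_multimapped, frac_long_gap, frac_noncanonical)
  .assert(all(fracs >= 0) && sum(fracs) <= 1 + 1e-12,
          "class fractions must be >= 0 and sum to <= 1")
  set.seed(seed)

  n_multi <- round(frac_multimapped * n_reads)
  n_gap <- round(frac_long_gap * n_reads)
  n_noncan <- round(frac_noncanonical * n_reads)
  if (n_multi + n_gap + n_noncan > n_reads)   # rounding overflow
    n_noncan <- n_reads - n_multi - n_gap
  n_good <- n_reads - n_multi - n_gap - n_noncan
  n_good_spliced <- n_good %/% 2
  n_good_flat <- n_good - n_good_spliced

  block <- 40L
  stride_splice <- block * 2L + gap_short + 20L
  n_splice_windows <- n_good_spliced + n_noncan

  len_splice <- max(1L, n_splice_windows) * stride_splice + 100L
  stride_long <- 4L
  len_long <- max(1L, n_gap) * stride_long + block * 2L + gap_long + 100L
  len_flat <- 10000L

  bases <- c("A", "C", "G", "T")
  chars <- list(chr_splice = sample(bases, len_splice, replace = TRUE),
                chr_long = sample(bases, len_long, replace = TRUE),
                chr_flat = sample(bases, len_flat, replace = TRUE))

  # canonical donor/acceptor pairs, forward and reverse genomic orientation
  canon_fwd <- list(c("G", "T", "A", "G"), c("G", "C", "A", "G"),
                    c("A", "T", "A", "C"))
  canon_rev <- list(c("C", "T", "A", "C"), c("C", "T", "G", "C"),
                    c("G", "T", "A", "T"))
  canon_all <- c(canon_fwd, canon_rev)

  classes <- sample(c(rep("multimapped", n_multi), rep("long_gap", n_gap),
                      rep("noncanonical", n_noncan),
                      rep("good_spliced", n_good_spliced),
                      rep("good_unspliced", n_good_flat)))
  ids <- sprintf("r%06d", seq_len(n_reads))

  # pass 1: lay out reads and plant junction motifs
  chrom <- character(n_reads); pos <- integer(n_reads)
  gap <- integer(n_reads); nh <- rep(1L, n_reads)
  splice_slot <- 0L; long_slot <- 0L
  flat_starts <- sample.int(len_flat - 2L * block,
                            sum(classes %in% c("multimapped", "good_unspliced")),
                            replace = TRUE)
  flat_i <- 0L
  for (i in seq_len(n_reads)) {
    cls <- classes[i]
    if (cls %in% c("multimapped", "good_unspliced")) {
      flat_i <- flat_i + 1L
      chrom[i] <- "chr_flat"; pos[i] <- flat_starts[flat_i]; gap[i] <- 0L
      if (cls == "multimapped") nh[i] <- 2L
    } else if (cls == "long_gap") {
      long_slot <- long_slot + 1L
      chrom[i] <- "chr_long"
      pos[i] <- (long_slot - 1L) * stride_long + 1L
      gap[i] <- gap_long
      m <- canon_fwd[[1L + (long_slot %% 3L)]]
    } else {
      splice_slot <- splice_slot + 1L
      chrom[i] <- "chr_splice"
      pos[i] <- (splice_slot - 1L) * stride_splice + 1L
      gap[i] <- gap_short
      m <- if (cls == "noncanonical") c("A", "A", "A", "A")
           else canon_all[[1L + (splice_slot %% length(canon_all))]]
    }
    if (gap[i] > 0L) {
      d <- pos[i] + block                 # first intron base
      a <- pos[i] + block + gap[i] - 1L   # last intron base
      chars[[chrom[i]]][c(d, d + 1L, a - 1L, a)] <- m
    }
  }

  chrom_seq <- vapply(chars, paste, character(1), collapse = "")

  # pass 2: emit records with sequences read back from the genome
  cigar <- ifelse(gap > 0L, sprintf("%dM%dN%dM", block, gap, block),
                  sprintf("%dM", 2L * block))
  seq1 <- substr(chrom_seq[chrom], pos, pos + block - 1L)
  seq2 <- substr(chrom_seq[chrom], pos + block + gap,
                 pos + block + gap + block - 1L)
  recs <- paste(ids, 0L, chrom, pos, 255L, cigar, "*", 0L, 0L,
                paste0(seq1, seq2), strrep("I", 2L * block),
                sprintf("NH:i:%d", nh), sep = "\t")

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_seq),
                      nchar(chrom_seq)))
  genome <- Biostrings::DNAStringSet(chrom_seq)
  list(sam = c(header, recs), genome = genome,
       expected_pass = ids[classes %in% c("good_spliced", "good_unspliced")],
       reads = data.frame(read_id = ids, class = classes,
                          stringsAsFactors = FALSE))
}

#' Write a simulated SAM + genome FASTA pair
#'
#' @param sim result of [simulate_sam()].
#' @param sam_path,fasta_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_sam_fixture <- function(sim, sam_path, fasta_path) {
  writeLines(sim$sam, sam_path)
  Biostrings::writeXStringSet(sim$genome, fasta_path)
  invisible(list(sam = sam_path, fasta = fasta_path))
}
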