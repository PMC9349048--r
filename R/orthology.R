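# Reciprocal-best-hit orthology from alignment bit scores, and priority-based
# GO transfer.

#' Read a BLAST tabular (outfmt 6) score table
#'
#' Accepts either the standard 12-column outfmt-6 layout (qseqid, sseqid,
#' ..., bitscore last) or any table carrying columns named `qseqid`,
#' `sseqid`, `bitscore`. Multiple HSPs per (query, subject) pair are reduced
#' to the maximum bit score.
#'
#' @param x path to a tab-separated file, or a data.frame.
#' @return data.frame with columns `qseqid`, `sseqid`, `bitscore`, one row
#'   per (query, subject) pair.
#' @export
read_blast_scores <- function(x) {
  df <- if (is.character(x))
    as.data.frame(data.table::fread(x, header = FALSE, sep = "\t"))
  else as.data.frame(x)
  if (!all(c("qseqid", "sseqid", "bitscore") %in% names(df))) {
    .assert(ncol(df) %in% c(3L, 12L),
            "read_blast_scores: expected 3 or 12 unnamed columns, got %d",
            ncol(df))
    df <- data.frame(qseqid = df[[1]], sseqid = df[[2]],
                     bitscore = df[[ncol(df)]])
  }
  df <- df[, c("qseqid", "sseqid", "bitscore")]
  .assert(all(df$bitscore > 0), "read_blast_scores: bit scores must be > 0")
  if (nrow(df) == 0L) return(df)
  dt <- data.table::as.data.table(df)
  out <- dt[, list(bitscore = max(bitscore)), by = c("qseqid", "sseqid")]
  as.data.frame(out)
}

# Best hit per query; queries whose maximum bit score is tied between several
# subjects are dropped entirely (deterministic orthology, no arbitrary
# tie-break).
#' @noRd
.best_hits <- function(tab) {
  dt <- data.table::as.data.table(tab)
  best <- dt[, {
    mx <- max(bitscore)
    hits <- sseqid[bitscore == mx]
    if (length(hits) == 1L) list(sseqid = hits) else list(sseqid = NA_character_)
  }, by = "qseqid"]
  best <- best[!is.na(sseqid)]
  setNames(best$sseqid, best$qseqid)
}

#' One-to-one orthologues by reciprocal best hit
#'
#' A pair (x, y) is kept when y is x's unique highest-bit-score hit in
#' `a_vs_b` and x is y's unique highest-scoring hit in `b_vs_a`. Genes whose
#' best score is tied between several partners are excluded.
#'
#' @param a_vs_b,b_vs_a score tables (see [read_blast_scores()]) for the two
#'   alignment directions.
#' @param species optional length-2 character vector of species labels.
#' @return data.frame of class `ortho_map` with columns `gene_a`, `gene_b`;
#'   each gene appears in at most one pair.
#' @export
reciprocal_best_hits <- function(a_vs_b, b_vs_a, species = c("A", "B")) {
  a_vs_b <- read_blast_scores(a_vs_b)
  b_vs_a <- read_blast_scores(b_vs_a)
  if (nrow(a_vs_b) == 0L || nrow(b_vs_a) == 0L) {
    warning("reciprocal_best_hits: empty score table; empty orthologue map")
    out <- data.frame(gene_a = character(0), gene_b = character(0))
  } else {
    best_ab <- .best_hits(a_vs_b)
    best_ba <- .best_hits(b_vs_a)
    cand <- names(best_ab)
    keep <- !is.na(best_ba[best_ab[cand]]) &
      best_ba[best_ab[cand]] == cand
    keep[is.na(keep)] <- FALSE
    out <- data.frame(gene_a = cand[keep],
                      gene_b = unname(best_ab[cand[keep]]))
  }
  attr(out, "species") <- species
  class(out) <- c("ortho_map", "data.frame")
  out
}

#' Transfer GO annotation through orthologues by species priority
#'
#' Each target gene takes the GO term set of its orthologue in the
#' highest-priority reference species in which a pair exists. Genes with no
#' orthologue in any reference fall back to their best alignment hit's terms,
#' when a fallback table is supplied; otherwise they stay unannotated.
#'
#' @param ortho_maps list of [reciprocal_best_hits()] maps, highest priority
#'   first; `gene_a` is the target-species gene in each.
#' @param go_maps list (same length/order) mapping reference-species gene ->
#'   character vector of GO ids, or data.frames with columns `gene`, `term`.
#' @param target_genes character vector of genes to annotate.
#' @param fallback_hits optional data.frame `gene`, `hit` of best alignment
#'   hits into `fallback_go`.
#' @param fallback_go optional GO map (same formats) for the fallback hits.
#' @return named list: target gene -> character vector of GO ids (possibly
#'   empty).
#' @export
transfer_go <- function(ortho_maps, go_maps, target_genes,
                        fallback_hits = NULL, fallback_go = NULL) {
  .assert(length(ortho_maps) == length(go_maps),
          "transfer_go: one GO map per orthologue map required")
  .as_go_list <- function(gm) {
    if (is.data.frame(gm)) gm <- split(as.character(gm$term),
                                       as.character(gm$gene))
    gm
  }
  go_maps <- lapply(go_maps, .as_go_list)
  fallback_go <- if (!is.null(fallback_go)) .as_go_list(fallback_go)
  out <- setNames(vector("list", length(target_genes)), target_genes)
  for (g in target_genes) {
    terms <- character(0)
    paired <- FALSE
    for (i in seq_along(ortho_maps)) {
      om <- ortho_maps[[i]]
      hit <- om$gene_b[om$gene_a == g]
      if (length(hit) == 1L) {
        # highest-priority species with a pair wins, even if its GO is empty
        terms <- go_maps[[i]][[hit]] %||% character(0)
        paired <- TRUE
        break
      }
    }
    if (!paired && !is.null(fallback_hits)) {
      fb <- fallback_hits$hit[fallback_hits$gene == g]
      if (length(fb) == 1L) terms <- fallback_go[[fb]] %||% character(0)
    }
    out[[g]] <- unique(terms)
  }
  out
}
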