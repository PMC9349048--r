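# GO over-representation with an expression-aware background.
#
# The background is every expressed gene that is not itself an up-regulated
# DEG: genes with mean cluster-level expression above a CP10K threshold
# across the clusters of interest, minus the DEG set. Each term is tested
# independently (no GO-graph propagation) with a one-sided Fisher's exact
# test on the four counts (DEGs in term, DEGs not, background in term,
# background not).

#' GO term over-representation for a set of up-regulated DEGs
#'
#' @param up_degs character vector of up-regulated DEG gene ids.
#' @param expr a [cluster_expression()] over the clusters of interest; the
#'   background is built from its genes.
#' @param go_map data.frame with columns `gene`, `term`, or a named list
#'   gene -> character vector of terms. Must annotate at least one DEG.
#' @param min_cp10k background expression threshold on the mean CP10K across
#'   the clusters of interest (default 1). Note `cluster_expression` values
#'   are on a per-million scale, i.e. 100 x CP10K.
#' @param fdr_cut,min_genes significance gates: `fdr < fdr_cut` and at least
#'   `min_genes` DEGs in the term (defaults 0.05 and 2).
#' @param alternative `"greater"` (over-representation, default) or
#'   `"two.sided"`.
#' @return data.frame with one row per tested term (terms annotated to >= 1
#'   DEG): `go_term`, `n_deg_in_term`, `n_deg`, `n_bg_in_term`, `n_bg`, `p`,
#'   `fdr`, `significant`.
#' @export
go_enrichment <- function(up_degs, expr, go_map, min_cp10k = 1,
                          fdr_cut = 0.05, min_genes = 2L,
                          alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  .assert(inherits(expr, "cluster_expression"),
          "expr must come from cluster_expression()")
  if (is.data.frame(go_map))
    go_map <- split(as.character(go_map$term), as.character(go_map$gene))
  mean_cp10k <- colMeans(expr$values) / 100   # values are 100 x CP10K
  expressed <- names(mean_cp10k)[mean_cp10k > min_cp10k]
  background <- setdiff(expressed, up_degs)
  .assert(length(background) > 0L, "go_enrichment: empty background")
  up_degs <- unique(up_degs)

  gene2terms <- go_map[intersect(names(go_map), c(up_degs, background))]
  term_of_deg <- unlist(go_map[intersect(up_degs, names(go_map))],
                        use.names = FALSE)
  terms <- sort(unique(term_of_deg))   # only terms with >= 1 DEG are tested
  .assert(length(terms) > 0L, "go_enrichment: no DEG carries a GO term")

  n_deg <- length(up_degs); n_bg <- length(background)
  rows <- lapply(terms, function(tt) {
    in_term <- names(gene2terms)[vapply(gene2terms, function(v) tt %in% v,
                                        logical(1))]
    a <- sum(up_degs %in% in_term)
    c_ <- sum(background %in% in_term)
    b <- n_deg - a; d <- n_bg - c_
    p <- if (alternative == "greater")
      stats::phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)
    else .fisher_p2(a, b, c_, d)
    data.frame(go_term = tt, n_deg_in_term = a, n_deg = n_deg,
               n_bg_in_term = c_, n_bg = n_bg, p = p)
  })
  res <- do.call(rbind, rows)
  res$fdr <- .bh(res$p)
  res$significant <- res$fdr < fdr_cut & res$n_deg_in_term >= min_genes
  res[order(res$p), ]
}
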