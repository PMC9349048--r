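# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.assert <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = call.)
}

# UMI matrices travel as SingleCellExperiment objects: sparse genes x cells
# counts in assay "counts", per-cell metadata (species, replicate, phenotype,
# cluster) in colData.

#' Build a UMI matrix container
#'
#' Wraps a sparse genes-by-cells UMI count matrix and its per-cell metadata in
#' a [SingleCellExperiment::SingleCellExperiment]. This is the common currency
#' of the package: QC, expression summaries, marker detection and pseudo-cell
#' construction all consume it.
#'
#' @param counts genes x cells matrix of non-negative integer UMI counts
#'   (coerced to a sparse `dgCMatrix`). Row and column names are required.
#' @param meta `data.frame` of per-cell metadata, one row per column of
#'   `counts`. Typical columns: `species`, `replicate`, `phenotype`,
#'   `cluster`.
#' @param rowdata optional `data.frame` of per-gene metadata.
#' @return a `SingleCellExperiment` with assay `"counts"`.
#' @export
umi_matrix <- function(counts, meta = NULL, rowdata = NULL) {
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  .assert(!is.null(rownames(counts)) && !is.null(colnames(counts)),
          "umi_matrix: counts must carry gene (row) and cell (column) names")
  .assert(length(counts@x) == 0L || min(counts@x) >= 0,
          "umi_matrix: counts must be non-negative")
  if (is.null(meta)) meta <- data.frame(row.names = colnames(counts))
  .assert(nrow(meta) == ncol(counts),
          "umi_matrix: meta has %d rows but counts has %d cells",
          nrow(meta), ncol(counts))
  rownames(meta) <- colnames(counts)
  args <- list(assays = list(counts = counts),
               colData = S4Vectors::DataFrame(meta))
  if (!is.null(rowdata)) args$rowData <- S4Vectors::DataFrame(rowdata)
  do.call(SingleCellExperiment::SingleCellExperiment, args)
}

#' @noRd
.counts <- function(x) {
  if (is(x, "SummarizedExperiment"))
    return(SummarizedExperiment::assay(x, "counts"))
  as(as(x, "CsparseMatrix"), "dMatrix")
}

#' @noRd
.coldata <- function(x, column) {
  .assert(is(x, "SummarizedExperiment"),
          "expected a SingleCellExperiment when labels are taken from metadata")
  cd <- SummarizedExperiment::colData(x)
  .assert(column %in% colnames(cd), "no '%s' column in cell metadata", column)
  as.character(cd[[column]])
}

# Benjamini-Hochberg, kept as a named wrapper so the adjustment used is
# explicit at every call site.
#' @noRd
.bh <- function(p) p.adjust(p, method = "BH")

# Round half away from zero (base round() is banker's rounding).
#' @noRd
.round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' @noRd
.write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @noRd
.md5_of <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}
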