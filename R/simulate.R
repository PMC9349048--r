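# Synthetic two-species atlas generator with known ground truth.
#
# The generator states a world modelled on a whole-brain snRNA-seq atlas of a
# social insect: four adult phenotypes sequenced as 5 + 4 + 4 + 4 pooled
# replicates, 43 transcriptomic cell clusters, and a second species sharing
# most of its gene repertoire through one-to-one orthologues. Every default
# below is either that stated design or a value documented in the methods
# vignette; tests and examples pass smaller configs explicitly.

#' Configuration for the synthetic atlas generator
#'
#' @param n_species 1 or 2 species to simulate.
#' @param n_clusters number of cell clusters per species (shared programs).
#' @param n_genes number of nuclear genes per species (mitochondrial genes are
#'   added on top, see `mito_genes`).
#' @param frac_orthologous fraction of genes with a one-to-one orthologue in
#'   the other species.
#' @param n_marker_genes_per_cluster genes whose rate is multiplied by
#'   `marker_fold` in their own cluster; marker sets are disjoint across
#'   clusters.
#' @param marker_fold expression multiplier (> 0) for marker genes in their
#'   cluster.
#' @param phenotypes named integer vector: replicate count per phenotype.
#'   Default is the 17-sample design (worker 5, queen 4, gyne 4, male 4).
#' @param cells_per_replicate nuclei drawn per replicate.
#' @param base_composition simplex over clusters (default uniform); must sum
#'   to 1 within 1e-9.
#' @param planted_effects named list mapping cluster label to a named numeric
#'   vector of per-phenotype abundance multipliers (> 0). Clusters/phenotypes
#'   not listed default to 1.
#' @param mito_genes number of mitochondrial genes appended to the gene set.
#' @param mito_rate_share expected fraction of each cell's UMIs coming from
#'   mitochondrial genes (kept under the 1% QC gate by default).
#' @param mean_umi_per_cell mean of the per-cell total-UMI distribution.
#' @param dispersion log-scale s.d. of the per-cell total-UMI log-normal.
#' @param replicate_concentration Dirichlet concentration of the per-replicate
#'   composition jitter (larger = tighter replicates).
#' @param species_noise_sd log-normal s.d. of the per-gene rate divergence
#'   between orthologous genes of the two species.
#' @param seed integer seed; fully determines the output.
#' @return an `atlas_sim_config` list, validated.
#' @export
atlas_sim_config <- function(n_species = 2L,
                             n_clusters = 43L,
                             n_genes = 12000L,
                             frac_orthologous = 0.8,
                             n_marker_genes_per_cluster = 25L,
                             marker_fold = 8,
                             phenotypes = c(worker = 5L, queen = 4L,
                                            gyne = 4L, male = 4L),
                             cells_per_replicate = 12000L,
                             base_composition = NULL,
                             planted_effects = list(),
                             mito_genes = 13L,
                             mito_rate_share = 0.005,
                             mean_umi_per_cell = 1500,
                             dispersion = 0.35,
                             replicate_concentration = 200,
                             species_noise_sd = 0.15,
                             seed = 1L) {
  cfg <- list(n_species = as.integer(n_species),
              n_clusters = as.integer(n_clusters),
              n_genes = as.integer(n_genes),
              frac_orthologous = frac_orthologous,
              n_marker_genes_per_cluster = as.integer(n_marker_genes_per_cluster),
              marker_fold = marker_fold,
              phenotypes = phenotypes,
              cells_per_replicate = as.integer(cells_per_replicate),
              base_composition = base_composition,
              planted_effects = planted_effects,
              mito_genes = as.integer(mito_genes),
              mito_rate_share = mito_rate_share,
              mean_umi_per_cell = mean_umi_per_cell,
              dispersion = dispersion,
              replicate_concentration = replicate_concentration,
              species_noise_sd = species_noise_sd,
              seed = as.integer(seed))
  .assert(cfg$n_species %in% 1:2, "n_species must be 1 or 2")
  .assert(cfg$n_clusters >= 1L && cfg$n_genes >= 1L, "need >= 1 cluster/gene")
  .assert(cfg$frac_orthologous >= 0 && cfg$frac_orthologous <= 1,
          "frac_orthologous must be in [0, 1]")
  .assert(cfg$marker_fold > 0, "marker_fold must be > 0")
  .assert(cfg$n_marker_genes_per_cluster * cfg$n_clusters <= cfg$n_genes,
          "markers exceed gene count: %d clusters x %d markers > %d genes",
          cfg$n_clusters, cfg$n_marker_genes_per_cluster, cfg$n_genes)
  .assert(length(cfg$phenotypes) >= 1L && !is.null(names(cfg$phenotypes)) &&
            all(cfg$phenotypes >= 1L),
          "phenotypes must be a named vector of replicate counts >= 1")
  if (is.null(cfg$base_composition))
    cfg$base_composition <- rep(1 / cfg$n_clusters, cfg$n_clusters)
  .assert(length(cfg$base_composition) == cfg$n_clusters &&
            abs(sum(cfg$base_composition) - 1) <= 1e-9 &&
            all(cfg$base_composition > 0),
          "base_composition must be a positive simplex over %d clusters",
          cfg$n_clusters)
  for (eff in cfg$planted_effects)
    .assert(all(eff > 0), "planted abundance multipliers must be > 0")
  .assert(cfg$mito_rate_share >= 0 && cfg$mito_rate_share < 1,
          "mito_rate_share must be in [0, 1)")
  .assert(cfg$mean_umi_per_cell > 0 && cfg$dispersion > 0 &&
            cfg$replicate_concentration > 0,
          "mean_umi_per_cell, dispersion, replicate_concentration must be > 0")
  class(cfg) <- "atlas_sim_config"
  cfg
}

# Cluster labels follow the atlas convention c1..cK.
#' @noRd
.cluster_labels <- function(k) paste0("c", seq_len(k))

# Per-phenotype expected composition: base x planted multipliers, renormalized.
#' @noRd
.phenotype_composition <- function(cfg, phenotype) {
  p <- cfg$base_composition
  names(p) <- .cluster_labels(cfg$n_clusters)
  for (cl in names(cfg$planted_effects)) {
    eff <- cfg$planted_effects[[cl]]
    if (phenotype %in% names(eff)) p[cl] <- p[cl] * eff[[phenotype]]
  }
  p / sum(p)
}

#' @noRd
.rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1  # degenerate guard
  g / sum(g)
}

# Draw one species' cells. `rates` is genes x clusters rate matrix (columns
# sum to 1). Returns sparse counts plus metadata.
#' @noRd
.simulate_species_cells <- function(cfg, species, rates, gene_ids) {
  clusters <- .cluster_labels(cfg$n_clusters)
  cell_meta <- list(); triplets_i <- list(); triplets_j <- list()
  triplets_x <- list(); idx <- 0L; cell0 <- 0L
  comp_counts <- list()
  for (ph in names(cfg$phenotypes)) {
    p_ph <- .phenotype_composition(cfg, ph)
    for (r in seq_len(cfg$phenotypes[[ph]])) {
      sample_id <- sprintf("%s_%s_r%d", species, ph, r)
      p_rep <- .rdirichlet1(cfg$replicate_concentration * p_ph)
      n_by_cluster <- drop(rmultinom(1, cfg$cells_per_replicate, p_rep))
      comp_counts[[sample_id]] <- setNames(n_by_cluster, clusters)
      cl_of_cell <- rep(clusters, n_by_cluster)
      n_cells <- length(cl_of_cell)
      totals <- pmax(1L, as.integer(round(rlnorm(
        n_cells,
        meanlog = log(cfg$mean_umi_per_cell) - cfg$dispersion^2 / 2,
        sdlog = cfg$dispersion))))
      for (k in seq_along(clusters)) {
        cells_k <- which(cl_of_cell == clusters[k])
        if (!length(cells_k)) next
        # rmultinom needs a common size, so draw per cell (totals differ)
        for (ci in seq_along(cells_k)) {
          cnt <- drop(rmultinom(1, totals[cells_k[ci]], rates[, k]))
          nz <- which(cnt > 0)
          if (!length(nz)) next
          idx <- idx + 1L
          triplets_i[[idx]] <- nz
          triplets_j[[idx]] <- rep.int(cell0 + cells_k[ci], length(nz))
          triplets_x[[idx]] <- cnt[nz]
        }
      }
      cell_meta[[sample_id]] <- data.frame(
        species = species, phenotype = ph, replicate = sample_id,
        cluster = cl_of_cell, total_umi_drawn = totals,
        stringsAsFactors = FALSE)
      cell0 <- cell0 + n_cells
    }
  }
  meta <- do.call(rbind, cell_meta)
  rownames(meta) <- NULL
  meta$cell_id <- sprintf("%s_cell%06d", species, seq_len(nrow(meta)))
  counts <- Matrix::sparseMatrix(
    i = unlist(triplets_i), j = unlist(triplets_j), x = unlist(triplets_x),
    dims = c(length(gene_ids), nrow(meta)),
    dimnames = list(gene_ids, meta$cell_id))
  comp <- do.call(rbind, comp_counts)
  list(counts = counts, meta = meta, composition = comp)
}

#' Simulate a one- or two-species single-nucleus atlas with ground truth
#'
#' Draws, per replicate, a Dirichlet-jittered cluster composition (base
#' composition times any planted per-phenotype multipliers, renormalized);
#' per cell, a log-normal total UMI count and a multinomial gene vector from a
#' cluster-specific rate program in which that cluster's marker genes are
#' up-weighted by `marker_fold`. Orthologous genes share rate programs across
#' species up to log-normal noise; mitochondrial genes receive a fixed small
#' rate share. Output is fully determined by `config$seed`.
#'
#' @param config an [atlas_sim_config()].
#' @return a list of class `atlas_sim` with elements
#'   \describe{
#'     \item{species}{named list of `SingleCellExperiment` UMI matrices, one
#'       per species (`"A"`, and `"B"` if two species). `rowData` carries
#'       `is_mito` and `marker_of`.}
#'     \item{composition}{[composition_table()] of species A (samples x
#'       clusters cell counts with the phenotype design).}
#'     \item{truth}{ground truth: `homolog_pairs` (data.frame of true
#'       cross-species cluster matches), `true_markers` (per species, cluster
#'       -> gene ids), `affected_clusters` (clusters with planted composition
#'       effects), `ortho_pairs` (data.frame gene_a/gene_b), `mito_genes`
#'       (per species).}
#'     \item{config}{the config used.}
#'   }
#' @export
simulate_atlas <- function(config) {
  .assert(inherits(config, "atlas_sim_config"),
          "config must come from atlas_sim_config()")
  cfg <- config
  set.seed(cfg$seed)
  clusters <- .cluster_labels(cfg$n_clusters)

  n_nuc <- cfg$n_genes
  gene_ids_a <- c(sprintf("A_g%05d", seq_len(n_nuc)),
                  if (cfg$mito_genes > 0) sprintf("A_mt%02d", seq_len(cfg$mito_genes)))
  baseline_a <- rlnorm(n_nuc, meanlog = 0, sdlog = 1.5)

  # Disjoint marker sets, drawn uniformly over nuclear genes.
  marker_pool <- sample.int(n_nuc, cfg$n_clusters * cfg$n_marker_genes_per_cluster)
  marker_idx <- split(marker_pool,
                      factor(rep(seq_len(cfg$n_clusters),
                                 each = cfg$n_marker_genes_per_cluster),
                             levels = seq_len(cfg$n_clusters)))
  names(marker_idx) <- clusters

  ortho_idx <- sort(sample.int(n_nuc, round(cfg$frac_orthologous * n_nuc)))

  .rates_for <- function(baseline) {
    rates <- matrix(baseline, nrow = n_nuc, ncol = cfg$n_clusters)
    for (k in seq_len(cfg$n_clusters))
      rates[marker_idx[[k]], k] <- rates[marker_idx[[k]], k] * cfg$marker_fold
    # append mito genes carrying a fixed expected share of each cell's UMIs
    rates <- sweep(rates, 2, colSums(rates), "/") * (1 - cfg$mito_rate_share)
    if (cfg$mito_genes > 0) {
      mito <- matrix(cfg$mito_rate_share / cfg$mito_genes,
                     nrow = cfg$mito_genes, ncol = cfg$n_clusters)
      rates <- rbind(rates, mito)
    }
    rates
  }

  .rowdata_for <- function(gene_ids) {
    marker_of <- rep(NA_character_, length(gene_ids))
    for (k in clusters) marker_of[marker_idx[[k]]] <- k
    data.frame(gene = gene_ids,
               is_mito = grepl("_mt", gene_ids, fixed = TRUE),
               marker_of = marker_of, row.names = gene_ids)
  }

  rates_a <- .rates_for(baseline_a)
  species_out <- list()
  sim_a <- .simulate_species_cells(cfg, "A", rates_a, gene_ids_a)
  species_out$A <- umi_matrix(sim_a$counts, sim_a$meta,
                              rowdata = .rowdata_for(gene_ids_a))

  truth <- list(
    homolog_pairs = data.frame(cluster_a = character(0),
                               cluster_b = character(0)),
    true_markers = list(A = lapply(marker_idx, function(ix) gene_ids_a[ix])),
    affected_clusters = character(0),
    ortho_pairs = data.frame(gene_a = character(0), gene_b = character(0)),
    mito_genes = list(A = gene_ids_a[grepl("_mt", gene_ids_a, fixed = TRUE)]))

  affected <- vapply(names(cfg$planted_effects), function(cl)
    any(cfg$planted_effects[[cl]] != 1), logical(1))
  truth$affected_clusters <- names(cfg$planted_effects)[affected]

  if (cfg$n_species == 2L) {
    gene_ids_b <- c(sprintf("B_g%05d", seq_len(n_nuc)),
                    if (cfg$mito_genes > 0) sprintf("B_mt%02d", seq_len(cfg$mito_genes)))
    baseline_b <- rlnorm(n_nuc, meanlog = 0, sdlog = 1.5)
    # orthologous genes inherit species A's program up to log-normal noise
    baseline_b[ortho_idx] <- baseline_a[ortho_idx] *
      rlnorm(length(ortho_idx), 0, cfg$species_noise_sd)
    rates_b <- .rates_for(baseline_b)
    sim_b <- .simulate_species_cells(cfg, "B", rates_b, gene_ids_b)
    species_out$B <- umi_matrix(sim_b$counts, sim_b$meta,
                                rowdata = .rowdata_for(gene_ids_b))
    truth$homolog_pairs <- data.frame(cluster_a = clusters,
                                      cluster_b = clusters)
    truth$true_markers$B <- lapply(marker_idx, function(ix) gene_ids_b[ix])
    truth$ortho_pairs <- data.frame(gene_a = gene_ids_a[ortho_idx],
                                    gene_b = gene_ids_b[ortho_idx])
    truth$mito_genes$B <- gene_ids_b[grepl("_mt", gene_ids_b, fixed = TRUE)]
  }

  comp <- composition_table(sim_a$composition,
                            phenotype = sim_a$meta$phenotype[
                              match(rownames(sim_a$composition),
                                    sim_a$meta$replicate)])

  structure(list(species = species_out, composition = comp,
                 truth = truth, config = cfg),
            class = "atlas_sim")
}

#' Write the synthetic-atlas inputs to disk
#'
#' Emits, per species, a Matrix Market `matrix.mtx` with `genes.tsv` and
#' `cells.tsv` sidecars, plus `composition.tsv`, `samples.tsv` and the ground
#' truth as JSON.
#'
#' @param sim result of [simulate_atlas()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_atlas_inputs <- function(sim, dir) {
  .assert(inherits(sim, "atlas_sim"), "sim must come from simulate_atlas()")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(sim$species)) {
    sce <- sim$species[[sp]]
    spdir <- file.path(dir, sp)
    dir.create(spdir, showWarnings = FALSE)
    Matrix::writeMM(.counts(sce), file.path(spdir, "matrix.mtx"))
    .write_tsv(as.data.frame(SummarizedExperiment::rowData(sce)),
               file.path(spdir, "genes.tsv"))
    cd <- as.data.frame(SummarizedExperiment::colData(sce))
    cd$cell_id <- colnames(sce)
    .write_tsv(cd, file.path(spdir, "cells.tsv"))
  }
  comp <- sim$composition
  .write_tsv(data.frame(sample = rownames(comp$counts),
                        as.data.frame(comp$counts), check.names = FALSE),
             file.path(dir, "composition.tsv"))
  .write_tsv(comp$samples, file.path(dir, "samples.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
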