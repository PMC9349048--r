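# End-to-end orchestration: a single config drives simulation, QC, marker
# detection, cross-dataset AUROC mapping, correspondence network and
# compositional testing, with digest-based caching of stage artifacts and a
# machine-readable manifest.

#' Default pipeline configuration
#'
#' Thresholds default to the atlas decision rules (QC 200-2,000 genes and
#' 1% mitochondrial UMIs; marker gates min.pct 0.25 / log-FC 0.25; DEG gates
#' FDR 0.05, fold 1.25, 20% expressed; AUROC edges > 0.80 with a 0.05
#' second-hit gap; compositional FDR 0.2 with fold > 1.3). The synthetic
#' input defaults to a small two-species demo so a bare run finishes on a
#' laptop; pass your own `sim` block for larger worlds.
#'
#' @return nested list of defaults; see [run_config()].
#' @export
default_run_config <- function() {
  list(
    out_dir = "atlas_run",
    seed = 1L,
    stages = list(simulate = TRUE, qc = TRUE, markers = TRUE,
                  crossmap = TRUE, network = TRUE, composition = TRUE),
    sim = list(n_species = 2L, n_clusters = 8L, n_genes = 1500L,
               frac_orthologous = 0.8, n_marker_genes_per_cluster = 15L,
               marker_fold = 8, phenotypes = c(ctrl = 3L, case = 3L),
               cells_per_replicate = 800L, mito_genes = 13L,
               mean_umi_per_cell = 1200, dispersion = 0.35),
    qc = list(min_genes = 200L, max_genes = 2000L, max_mito_frac = 0.01),
    markers = list(min_pct = 0.25, min_logfc = 0.25, positive_only = TRUE),
    degs = list(fdr_cut = 0.05, min_fold = 1.25, min_pct = 0.20),
    crossmap = list(group_size = 10L, n_top_genes = NULL),
    network = list(min_auroc = 0.80, second_hit_gap = 0.05),
    composition = list(groups = c("ctrl", "case"), reference = "auto",
                       fdr_level = 0.2, min_fold = 1.3)
  )
}

#' @noRd
.merge_config <- function(defaults, user, path = "") {
  .assert(is.list(user), "config section '%s' must be a mapping", path)
  unknown <- setdiff(names(user), names(defaults))
  .assert(length(unknown) == 0L,
          "unknown config key(s)%s: %s",
          if (nzchar(path)) paste0(" in '", path, "'") else "",
          paste(unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        k != "sim") {
      defaults[[k]] <- .merge_config(defaults[[k]], as.list(user[[k]]),
                                     paste0(path, k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Build and validate a pipeline configuration
#'
#' @param ... named overrides of [default_run_config()] entries (nested
#'   lists merge; unknown keys are rejected before any compute).
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- .merge_config(default_run_config(), list(...))
  for (nm in c("min_genes", "max_genes")) {
    v <- cfg$qc[[nm]]
    .assert(is.numeric(v) && length(v) == 1L && v >= 0,
            "config: qc.%s must be a single non-negative number", nm)
  }
  num1 <- function(section, nm) {
    v <- cfg[[section]][[nm]]
    .assert(is.numeric(v) && length(v) == 1L && is.finite(v),
            "config: %s.%s must be a single number", section, nm)
  }
  num1("qc", "max_mito_frac"); num1("markers", "min_pct")
  num1("markers", "min_logfc"); num1("degs", "fdr_cut")
  num1("degs", "min_fold"); num1("degs", "min_pct")
  num1("crossmap", "group_size"); num1("network", "min_auroc")
  num1("network", "second_hit_gap"); num1("composition", "fdr_level")
  num1("composition", "min_fold")
  .assert(is.numeric(cfg$seed) && length(cfg$seed) == 1L,
          "config: seed must be a single integer")
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of overrides; see [default_run_config()] for keys.
#' @return validated `run_config`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (!is.null(user$sim$phenotypes))
    user$sim$phenotypes <- unlist(user$sim$phenotypes)
  if (!is.null(user$composition$groups))
    user$composition$groups <- unlist(user$composition$groups)
  do.call(run_config, user %||% list())
}

#' Read synthetic-atlas inputs back from disk
#'
#' Counterpart of [write_atlas_inputs()].
#'
#' @param dir directory written by [write_atlas_inputs()].
#' @return list with `species` (SingleCellExperiments), `composition` and
#'   `truth`.
#' @export
read_atlas_inputs <- function(dir) {
  species <- list()
  for (sp in list.dirs(dir, recursive = FALSE, full.names = FALSE)) {
    spdir <- file.path(dir, sp)
    m <- as(Matrix::readMM(file.path(spdir, "matrix.mtx")), "CsparseMatrix")
    genes <- read.delim(file.path(spdir, "genes.tsv"))
    cells <- read.delim(file.path(spdir, "cells.tsv"))
    dimnames(m) <- list(genes$gene, cells$cell_id)
    species[[sp]] <- umi_matrix(m, cells[setdiff(names(cells), "cell_id")],
                                rowdata = genes)
  }
  comp_df <- read.delim(file.path(dir, "composition.tsv"), check.names = FALSE)
  samples <- read.delim(file.path(dir, "samples.tsv"))
  cnt <- as.matrix(comp_df[, -1, drop = FALSE])
  rownames(cnt) <- comp_df$sample
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  list(species = species,
       composition = composition_table(cnt, samples$phenotype,
                                       samples$replicate),
       truth = truth)
}

# Run one cached stage: skip when the hash matches and outputs exist.
#' @noRd
.run_stage <- function(state, name, params, outputs, compute, load,
                       deps = character(0)) {
  upstream <- vapply(state$manifest$stages[deps], function(s) s$hash,
                     character(1))
  hash <- .md5_of(list(params = params, upstream = upstream))
  stage_dir <- file.path(state$out_dir, name)
  hash_file <- file.path(stage_dir, ".stage_hash")
  paths <- file.path(stage_dir, outputs)
  cached <- file.exists(hash_file) &&
    identical(readLines(hash_file, warn = FALSE), hash) &&
    all(file.exists(paths))
  dir.create(stage_dir, recursive = TRUE, showWarnings = FALSE)
  if (cached) {
    message(sprintf("[%s] cached", name))
    state$data <- load(state$data, stage_dir)
  } else {
    message(sprintf("[%s] computing", name))
    state$data <- compute(state$data, stage_dir)
    writeLines(hash, hash_file)
  }
  state$manifest$stages[[name]] <- list(
    hash = hash, cached = cached,
    outputs = setNames(as.list(unname(tools::md5sum(paths))), outputs))
  state
}

#' Run the atlas pipeline end to end
#'
#' Executes the enabled stages in dependency order (simulate, qc, markers,
#' crossmap, network, composition), writing artifacts and a `manifest.json`
#' (seeds, thresholds, stage digests, artifact checksums, package version)
#' under `config$out_dir`. Stages whose parameters and upstream digests are
#' unchanged are reused from cache, so toggling a downstream threshold
#' re-runs only the stages below it.
#'
#' @param config a [run_config()] (or the result of [read_run_config()]).
#' @return the manifest, invisibly (list; also written as JSON).
#' @export
run_pipeline <- function(config) {
  .assert(inherits(config, "run_config"), "config must come from run_config()")
  state <- new.env(parent = emptyenv())
  state$out_dir <- config$out_dir
  state$manifest <- list(package = "crossatlas",
                         version = as.character(utils::packageVersion("crossatlas")),
                         seed = config$seed,
                         thresholds = config[c("qc", "markers", "degs",
                                               "crossmap", "network",
                                               "composition")],
                         stages = list())
  state$data <- list()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- config$stages

  if (isTRUE(st$simulate)) {
    sim_cfg <- do.call(atlas_sim_config,
                       c(config$sim, list(seed = config$seed)))
    state <- .run_stage(
      state, "simulate", params = unclass(sim_cfg),
      outputs = "inputs/ground_truth.json",
      compute = function(d, dir) {
        sim <- simulate_atlas(sim_cfg)
        write_atlas_inputs(sim, file.path(dir, "inputs"))
        d$sim <- sim
        d
      },
      load = function(d, dir) {
        d$sim <- read_atlas_inputs(file.path(dir, "inputs"))
        d
      })
  }

  if (isTRUE(st$qc)) {
    state <- .run_stage(
      state, "qc", params = config$qc, deps = "simulate",
      outputs = sprintf("qc_report_%s.tsv", names(state$data$sim$species)),
      compute = function(d, dir) {
        d$qc <- lapply(names(d$sim$species), function(sp) {
          sce <- d$sim$species[[sp]]
          mito <- rownames(sce)[SummarizedExperiment::rowData(sce)$is_mito]
          res <- qc_nuclei(sce, mito, config$qc$min_genes,
                           config$qc$max_genes, config$qc$max_mito_frac)
          .write_tsv(res$report, file.path(dir, sprintf("qc_report_%s.tsv", sp)))
          res$matrix
        })
        names(d$qc) <- names(d$sim$species)
        d
      },
      load = function(d, dir) {
        d$qc <- lapply(names(d$sim$species), function(sp) {
          rep <- read.delim(file.path(dir, sprintf("qc_report_%s.tsv", sp)))
          d$sim$species[[sp]][, rep$cell_id[rep$pass]]
        })
        names(d$qc) <- names(d$sim$species)
        d
      })
  }

  if (isTRUE(st$markers)) {
    state <- .run_stage(
      state, "markers", params = config$markers, deps = "qc",
      outputs = sprintf("markers_%s.tsv", names(state$data$qc)),
      compute = function(d, dir) {
        d$markers <- lapply(names(d$qc), function(sp) {
          mk <- find_markers(d$qc[[sp]],
                             min_pct = config$markers$min_pct,
                             min_logfc = config$markers$min_logfc,
                             positive_only = config$markers$positive_only)
          .write_tsv(mk, file.path(dir, sprintf("markers_%s.tsv", sp)))
          mk
        })
        names(d$markers) <- names(d$qc)
        d
      },
      load = function(d, dir) {
        d$markers <- lapply(names(d$qc), function(sp)
          read.delim(file.path(dir, sprintf("markers_%s.tsv", sp))))
        names(d$markers) <- names(d$qc)
        d
      })
  }

  two_species <- length(state$data$qc %||% list()) == 2L
  if (isTRUE(st$crossmap) && two_species) {
    state <- .run_stage(
      state, "crossmap", params = config$crossmap, deps = c("simulate", "qc", "markers"),
      outputs = c("auroc.tsv", "dendrogram.nwk"),
      compute = function(d, dir) {
        ortho <- d$sim$truth$ortho_pairs
        sig <- unique(c(
          ortho$gene_a[ortho$gene_a %in% d$markers$A$gene],
          ortho$gene_a[ortho$gene_b %in% d$markers$B$gene]))
        .assert(length(sig) > 0L, "crossmap: no orthologous marker genes")
        pa <- make_pseudocells(d$qc$A, group_size = config$crossmap$group_size,
                               seed = config$seed)
        b_counts <- .counts(d$qc$B)
        idx <- match(rownames(b_counts), ortho$gene_b)
        keep <- !is.na(idx)
        b_mapped <- b_counts[keep, , drop = FALSE]
        rownames(b_mapped) <- ortho$gene_a[idx[keep]]
        pb <- make_pseudocells(
          umi_matrix(b_mapped,
                     as.data.frame(SummarizedExperiment::colData(d$qc$B))),
          labels = .coldata(d$qc$B, "cluster"),
          group_size = config$crossmap$group_size, seed = config$seed + 1L)
        pa <- standardize_pseudocells(pa, sig)
        pb <- standardize_pseudocells(pb, sig)
        d$auroc <- mean_auroc_matrix(pa, pb)
        .write_tsv(data.frame(cluster = rownames(d$auroc),
                              as.data.frame(unclass(d$auroc),
                                            check.names = FALSE)),
                   file.path(dir, "auroc.tsv"))
        ape::write.tree(auroc_dendrogram(d$auroc),
                        file.path(dir, "dendrogram.nwk"))
        d
      },
      load = function(d, dir) {
        df <- read.delim(file.path(dir, "auroc.tsv"), check.names = FALSE)
        m <- as.matrix(df[, -1, drop = FALSE])
        rownames(m) <- df$cluster
        d$auroc <- structure(m, class = c("auroc_matrix", "matrix"),
                             datasets = c("A", "B"))
        d
      })
  }

  if (isTRUE(st$network) && two_species) {
    state <- .run_stage(
      state, "network", params = config$network, deps = "crossmap",
      outputs = c("edges.tsv", "edges.graphml"),
      compute = function(d, dir) {
        blk <- auroc_between_block(d$auroc, "A", "B")
        d$edges <- correspondence_network(blk,
                                          min_auroc = config$network$min_auroc,
                                          second_hit_gap = config$network$second_hit_gap)
        write_network(d$edges, file.path(dir, "edges.tsv"),
                      file.path(dir, "edges.graphml"))
        d
      },
      load = function(d, dir) {
        d$edges <- read.delim(file.path(dir, "edges.tsv"))
        d
      })
  }

  if (isTRUE(st$composition)) {
    state <- .run_stage(
      state, "composition", params = config$composition, deps = "simulate",
      outputs = "dm_calls.tsv",
      compute = function(d, dir) {
        calls <- dm_composition_test(
          d$sim$composition, groups = config$composition$groups,
          reference = config$composition$reference,
          fdr_level = config$composition$fdr_level,
          min_fold = config$composition$min_fold)
        .write_tsv(as.data.frame(calls), file.path(dir, "dm_calls.tsv"))
        d$calls <- calls
        d
      },
      load = function(d, dir) {
        d$calls <- read.delim(file.path(dir, "dm_calls.tsv"))
        d
      })
  }

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(state$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(state$manifest)
}

# ---------------------------------------------------------------------------
# Command-line entry point (see inst/cli/atlas.R).

#' @noRd
.cli_opts <- function(args) {
  opts <- list(); positional <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      .assert(i < length(args), "missing value for --%s", key)
      opts[[gsub("-", "_", key)]] <- args[i + 1L]
      i <- i + 2L
    } else {
      positional <- c(positional, a)
      i <- i + 1L
    }
  }
  list(opts = opts, positional = positional)
}

#' Command-line interface
#'
#' Subcommands: `run -c/--config cfg.yaml` (full pipeline), `simulate
#' --out DIR [--seed N]` (write synthetic inputs), `filter-sam --sam F
#' --genome F --out F` (read filter; writes passing ids and rule counts).
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return exit status, invisibly.
#' @export
atlas_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  .assert(length(args) >= 1L,
          "usage: atlas <run|simulate|filter-sam> [options]")
  cmd <- args[1]
  parsed <- .cli_opts(args[-1])
  o <- parsed$opts
  if (cmd == "run") {
    cfgfile <- o$config %||% o$c
    cfg <- if (!is.null(cfgfile)) read_run_config(cfgfile) else run_config()
    if (!is.null(o$out_dir)) cfg$out_dir <- o$out_dir
    run_pipeline(cfg)
  } else if (cmd == "simulate") {
    .assert(!is.null(o$out), "simulate: --out is required")
    cfg <- atlas_sim_config(n_species = 2L, n_clusters = 8L,
                            n_genes = 1500L,
                            phenotypes = c(ctrl = 3L, case = 3L),
                            cells_per_replicate = 800L,
                            seed = as.integer(o$seed %||% 1L))
    write_atlas_inputs(simulate_atlas(cfg), o$out)
  } else if (cmd == "filter-sam") {
    .assert(!is.null(o$sam) && !is.null(o$genome) && !is.null(o$out),
            "filter-sam: --sam, --genome and --out are required")
    res <- filter_alignments(o$sam, o$genome)
    .write_tsv(data.frame(read_id = res$pass), o$out)
    message(sprintf("kept %d/%d reads (multimapped %d, long_gap %d, noncanonical %d)",
                    length(res$pass), res$n_reads,
                    res$discard_counts["multimapped"],
                    res$discard_counts["long_gap"],
                    res$discard_counts["noncanonical"]))
  } else {
    stop(sprintf("unknown command '%s'", cmd), call. = FALSE)
  }
  invisible(0L)
}
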