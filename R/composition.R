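# Relative-abundance summaries and compositional differential-abundance
# testing across phenotypes, with convergence calls across species.
#
# The Bayesian spike-and-slab sampler of the reference compositional tool is
# replaced by a maximum-likelihood Dirichlet-multinomial likelihood-ratio
# test that keeps the same decision surface: a reference cluster whose group
# effects are fixed at zero, a Benjamini-Hochberg FDR gate, and a fold-change
# gate on pooled relative abundances. Downstream logic consumes only the
# binary calls, folds and directions.

#' Samples-by-clusters cell-count table with phenotype design
#'
#' @param counts samples x clusters matrix of non-negative integer cell
#'   counts; row names are sample ids, every sample total must be > 0.
#' @param phenotype phenotype label per sample.
#' @param replicate replicate id per sample (defaults to row names).
#' @return object of class `composition_table`: list with `counts` and
#'   `samples` (data.frame `sample`, `phenotype`, `replicate`).
#' @export
composition_table <- function(counts, phenotype, replicate = NULL) {
  counts <- as.matrix(counts)
  .assert(!is.null(rownames(counts)) && !is.null(colnames(counts)),
          "composition_table: counts needs sample row names and cluster column names")
  .assert(all(counts >= 0) && all(counts == round(counts)),
          "composition_table: counts must be non-negative integers")
  .assert(all(rowSums(counts) > 0), "composition_table: empty sample")
  .assert(length(phenotype) == nrow(counts), "one phenotype per sample")
  samples <- data.frame(sample = rownames(counts),
                        phenotype = as.character(phenotype),
                        replicate = replicate %||% rownames(counts),
                        row.names = NULL)
  structure(list(counts = counts, samples = samples),
            class = "composition_table")
}

#' Relative cluster abundances per phenotype
#'
#' `pooled` mode sums counts over a phenotype's replicates before dividing
#' (the convention used for headline percentages); `per_replicate` computes
#' percentages within each sample.
#'
#' @param table a [composition_table()].
#' @param mode `"pooled"` or `"per_replicate"`.
#' @param phenotypes phenotypes to include (default: all; unknown labels are
#'   an error).
#' @return matrix of percentages (rows: phenotypes or samples; columns:
#'   clusters). Rows sum to 100.
#' @export
relative_abundance <- function(table, mode = c("pooled", "per_replicate"),
                               phenotypes = NULL) {
  mode <- match.arg(mode)
  .assert(inherits(table, "composition_table"),
          "table must come from composition_table()")
  ph <- table$samples$phenotype
  if (is.null(phenotypes)) phenotypes <- unique(ph)
  .assert(all(phenotypes %in% ph),
          "unknown phenotype label(s): %s",
          paste(setdiff(phenotypes, ph), collapse = ", "))
  if (mode == "pooled") {
    pooled <- do.call(rbind, lapply(phenotypes, function(p)
      colSums(table$counts[ph == p, , drop = FALSE])))
    rownames(pooled) <- phenotypes
    return(pooled / rowSums(pooled) * 100)
  }
  keep <- ph %in% phenotypes
  m <- table$counts[keep, , drop = FALSE]
  m / rowSums(m) * 100
}

#' Radar-plot normalization of per-cluster abundance profiles
#'
#' Per cluster: the mean per-replicate relative abundance is computed for
#' each phenotype, then divided by the maximum across phenotypes, so the
#' highest phenotype maps to exactly 1.
#'
#' @param table a [composition_table()] with >= 2 phenotypes.
#' @return clusters x phenotypes matrix in \[0, 1\]; clusters absent from
#'   every sample yield a row of `NA` with a warning.
#' @export
radar_normalize <- function(table) {
  .assert(inherits(table, "composition_table"),
          "table must come from composition_table()")
  ph <- table$samples$phenotype
  phenos <- unique(ph)
  .assert(length(phenos) >= 2L, "radar_normalize: need >= 2 phenotypes")
  rel <- relative_abundance(table, "per_replicate")
  means <- do.call(cbind, lapply(phenos, function(p)
    colMeans(rel[ph == p, , drop = FALSE])))
  colnames(means) <- phenos
  mx <- apply(means, 1, max)
  absent <- mx == 0
  if (any(absent)) {
    warning(sprintf("radar_normalize: cluster(s) absent everywhere: %s",
                    paste(rownames(means)[absent], collapse = ", ")))
    means[absent, ] <- NA_real_
  }
  means[!absent, ] <- means[!absent, , drop = FALSE] / mx[!absent]
  means
}

#' Fold change of relative abundances with zero handling
#'
#' Ratio of the larger over the smaller relative abundance, with the
#' direction pointing at the larger side. A cluster present on one side only
#' reports an infinite fold (complete absence is a difference, not a ratio);
#' absent on both sides reports `NA`.
#'
#' @param rel_a,rel_b relative abundances (same clusters, any common scale).
#' @param labels length-2 labels used in `direction` (default `"a"`, `"b"`).
#' @return data.frame `cluster`, `fold`, `direction`.
#' @export
fold_change <- function(rel_a, rel_b, labels = c("a", "b")) {
  .assert(length(rel_a) == length(rel_b),
          "fold_change: inputs must cover the same clusters")
  cl <- names(rel_a) %||% as.character(seq_along(rel_a))
  fold <- ifelse(rel_a == 0 & rel_b == 0, NA_real_,
                 pmax(rel_a, rel_b) / pmin(rel_a, rel_b))
  direction <- ifelse(rel_a == 0 & rel_b == 0, NA_character_,
                      ifelse(rel_a > rel_b, labels[1],
                             ifelse(rel_b > rel_a, labels[2], "equal")))
  data.frame(cluster = cl, fold = fold, direction = direction,
             row.names = NULL)
}

# ---------------------------------------------------------------------------
# Dirichlet-multinomial likelihood machinery.
#
# Sample i in group g has counts y_i ~ DM(n_i, alpha_g) with
# log alpha_{g, j} = beta0_j + beta_{g, j}; the first group carries no
# effects and the reference cluster's effects are fixed at zero for every
# group. The multinomial coefficient is dropped (constant in the
# parameters).

#' @noRd
.dm_loglik_grad <- function(theta, Y, group, ref, constrained) {
  S <- nrow(Y); J <- ncol(Y); G <- nlevels(group)
  beta0 <- theta[seq_len(J)]
  eff <- matrix(0, G, J)
  free_j <- setdiff(seq_len(J), c(ref, constrained))
  if (G > 1L && length(free_j))
    eff[-1L, free_j] <- matrix(theta[-seq_len(J)], G - 1L, length(free_j))
  log_alpha <- matrix(beta0, G, J, byrow = TRUE) + eff
  alpha <- exp(log_alpha)
  gi <- as.integer(group)
  A <- rowSums(alpha)            # per group
  n_i <- rowSums(Y)
  ll <- 0
  galpha <- matrix(0, G, J)      # d ll / d alpha, accumulated per group
  for (i in seq_len(S)) {
    g <- gi[i]
    a <- alpha[g, ]
    ll <- ll + lgamma(A[g]) - lgamma(A[g] + n_i[i]) +
      sum(lgamma(a + Y[i, ]) - lgamma(a))
    galpha[g, ] <- galpha[g, ] + digamma(A[g]) - digamma(A[g] + n_i[i]) +
      digamma(a + Y[i, ]) - digamma(a)
  }
  gbeta <- galpha * alpha        # chain rule through exp
  grad0 <- colSums(gbeta)
  grad_eff <- if (G > 1L && length(free_j))
    as.vector(gbeta[-1L, free_j, drop = FALSE]) else numeric(0)
  list(ll = ll, grad = c(grad0, grad_eff))
}

# Moment-based starting point: a Dirichlet-multinomial concentration from
# the across-sample variance of proportions, per-cluster intercepts from the
# pooled composition, and effects from group log-ratio contrasts against the
# reference cluster.
#' @noRd
.dm_init <- function(Y, group, ref, free_j) {
  J <- ncol(Y); G <- nlevels(group)
  prop <- Y / rowSums(Y)
  p <- pmax(colMeans(prop), 0.5 / sum(Y))
  v <- apply(prop, 2, var)
  with_sig <- v > 0 & p < 1
  A_hat <- if (any(with_sig))
    stats::median(p[with_sig] * (1 - p[with_sig]) / v[with_sig]) - 1
  else 100
  A_hat <- min(max(A_hat, 2), 1e4)
  beta0 <- log(p * A_hat)
  eff <- numeric(0)
  if (G > 1L && length(free_j)) {
    eps <- 0.5
    base_lr <- log((colSums(Y[group == levels(group)[1], , drop = FALSE]) + eps) /
                     (sum(Y[group == levels(group)[1], ref]) + eps))
    eff <- unlist(lapply(levels(group)[-1], function(g) {
      lr <- log((colSums(Y[group == g, , drop = FALSE]) + eps) /
                  (sum(Y[group == g, ref]) + eps))
      (lr - base_lr)[free_j]
    }))
  }
  c(beta0, eff)
}

#' @noRd
.dm_fit <- function(Y, group, ref, constrained = integer(0), init = NULL) {
  J <- ncol(Y); G <- nlevels(group)
  free_j <- setdiff(seq_len(J), c(ref, constrained))
  if (is.null(init)) init <- .dm_init(Y, group, ref, free_j)
  # box bounds keep exp() finite and the digamma chain well-defined
  fit <- optim(init,
               fn = function(th) -.dm_loglik_grad(th, Y, group, ref,
                                                  constrained)$ll,
               gr = function(th) -.dm_loglik_grad(th, Y, group, ref,
                                                  constrained)$grad,
               method = "L-BFGS-B", lower = -25, upper = 25,
               control = list(maxit = 1000, factr = 1e4))
  if (fit$convergence != 0 && fit$convergence != 52)
    stop(sprintf(
      "dm_composition_test: optimizer did not converge (code %d)%s",
      fit$convergence,
      if (length(constrained))
        sprintf(" for the fit constraining cluster %d", constrained[1])
      else " for the full model"))
  list(loglik = -fit$value, par = fit$par, free_j = free_j)
}

#' @noRd
.auto_reference <- function(table, keep_samples) {
  cnt <- table$counts[keep_samples, , drop = FALSE]
  rel <- cnt / rowSums(cnt)
  everywhere <- colSums(cnt > 0) == nrow(cnt)
  .assert(any(everywhere),
          "dm_composition_test: no cluster is detected in every sample")
  cv <- apply(rel[, everywhere, drop = FALSE], 2,
              function(x) sd(x) / mean(x))
  names(which.min(cv))
}

#' Dirichlet-multinomial compositional differential-abundance test
#'
#' Fits a Dirichlet-multinomial regression with per-cluster log-abundance
#' intercepts and group effects, the reference cluster's effects fixed at
#' zero, and tests each remaining cluster's group effect with a likelihood
#' ratio test (df = groups - 1). P values are Benjamini-Hochberg adjusted
#' across tested clusters; a cluster is called significant when
#' `fdr < fdr_level` and the pooled-relative-abundance fold change exceeds
#' `min_fold`.
#'
#' @param table a [composition_table()].
#' @param groups length-2 character vector of phenotype labels to compare
#'   (each with >= 2 samples).
#' @param reference `"auto"` (the cluster detected in every sample with the
#'   smallest coefficient of variation of per-replicate relative abundance)
#'   or a cluster name present in all samples.
#' @param fdr_level FDR gate (0.2 for within-species phenotype contrasts,
#'   0.1 for the cross-species mode).
#' @param min_fold fold gate (1.3 within species, 2 between species).
#' @return data.frame of class `abundance_calls` with columns `cluster`,
#'   `statistic`, `p`, `fdr`, `fold`, `direction` (label of the group with
#'   the higher pooled abundance), `significant`; attribute `reference`
#'   names the reference cluster (reported with `NA` statistics). All-zero
#'   clusters are excluded with a warning.
#' @export
dm_composition_test <- function(table, groups, reference = "auto",
                                fdr_level = 0.2, min_fold = 1.3) {
  .assert(inherits(table, "composition_table"),
          "table must come from composition_table()")
  .assert(length(groups) == 2L, "exactly two groups are compared")
  ph <- table$samples$phenotype
  .assert(all(groups %in% ph), "unknown group label")
  keep <- ph %in% groups
  .assert(all(table(ph[keep]) >= 2L), ">= 2 samples per group required")
  Y <- table$counts[keep, , drop = FALSE]
  zero <- colSums(Y) == 0
  if (any(zero)) {
    warning(sprintf("dm_composition_test: all-zero cluster(s) excluded: %s",
                    paste(colnames(Y)[zero], collapse = ", ")))
    Y <- Y[, !zero, drop = FALSE]
  }
  group <- factor(ph[keep], levels = groups)
  if (identical(reference, "auto")) {
    reference <- .auto_reference(composition_table(Y, ph[keep]),
                                 rep(TRUE, nrow(Y)))
  }
  .assert(reference %in% colnames(Y) && all(Y[, reference] > 0),
          "reference cluster '%s' must be present in all samples", reference)
  ref <- match(reference, colnames(Y))

  full <- .dm_fit(Y, group, ref)
  tested <- setdiff(seq_len(ncol(Y)), ref)
  stat <- p <- rep(NA_real_, ncol(Y))
  for (j in tested) {
    drop_idx <- ncol(Y) + match(j, full$free_j)  # G = 2: one effect per cluster
    red <- .dm_fit(Y, group, ref, constrained = j,
                   init = full$par[-drop_idx])
    if (red$loglik > full$loglik + 1e-4) {
      # restricted fit found a better mode: lift it to a full-model start
      lifted <- append(red$par, 0, after = drop_idx - 1L)
      refit <- .dm_fit(Y, group, ref, init = lifted)
      if (refit$loglik > full$loglik) full <- refit
    }
    stat[j] <- max(0, 2 * (full$loglik - red$loglik))
    p[j] <- pchisq(stat[j], df = nlevels(group) - 1L, lower.tail = FALSE)
  }
  fdr <- rep(NA_real_, ncol(Y))
  fdr[tested] <- .bh(p[tested])

  pooled <- relative_abundance(table, "pooled", phenotypes = groups)
  fc <- fold_change(pooled[groups[1], colnames(Y)],
                    pooled[groups[2], colnames(Y)], labels = groups)
  res <- data.frame(cluster = colnames(Y), statistic = stat, p = p,
                    fdr = fdr, fold = fc$fold, direction = fc$direction,
                    significant = !is.na(fdr) & fdr < fdr_level &
                      !is.na(fc$fold) & fc$fold > min_fold,
                    row.names = NULL)
  attr(res, "reference") <- reference
  attr(res, "groups") <- groups
  class(res) <- c("abundance_calls", "data.frame")
  res
}

# Two-sided Fisher exact p for a 2x2 table, by enumeration of the
# margin-fixed hypergeometric distribution: sum the probabilities of all
# tables no more probable than the observed one (with the standard 1 + 1e-7
# relative tolerance on the comparison).
#' @noRd
.fisher_p2 <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  x <- max(0L, k - n):min(k, m)
  probs <- dhyper(x, m, n, k)
  dobs <- dhyper(a, m, n, k)
  sum(probs[probs <= dobs * (1 + 1e-7)])
}

#' Fisher's exact differential-abundance test on pooled counts
#'
#' For each cluster, a two-sided Fisher's exact test on the 2x2 table
#' (cells in cluster vs not, by group), Benjamini-Hochberg adjustment across
#' clusters, and the gates `fdr < fdr_cut` and relative-abundance fold
#' change `> min_fold`.
#'
#' @param counts_1,counts_2 named vectors of pooled per-cluster cell counts
#'   for the two groups (same clusters; totals must be > 0).
#' @param fdr_cut,min_fold the gates (defaults 0.001 and 1.3).
#' @param labels length-2 group labels for `direction`.
#' @return data.frame of class `abundance_calls`: `cluster`, `p`, `fdr`,
#'   `fold`, `direction`, `significant`.
#' @export
fisher_abundance_test <- function(counts_1, counts_2, fdr_cut = 0.001,
                                  min_fold = 1.3, labels = c("1", "2")) {
  .assert(length(counts_1) == length(counts_2) &&
            identical(names(counts_1), names(counts_2)),
          "fisher_abundance_test: groups must cover the same clusters")
  t1 <- sum(counts_1); t2 <- sum(counts_2)
  .assert(t1 > 0 && t2 > 0, "fisher_abundance_test: zero-total group")
  p <- vapply(seq_along(counts_1), function(j)
    .fisher_p2(counts_1[j], t1 - counts_1[j],
               counts_2[j], t2 - counts_2[j]), numeric(1))
  fdr <- .bh(p)
  fc <- fold_change(counts_1 / t1, counts_2 / t2, labels = labels)
  res <- data.frame(cluster = names(counts_1) %||%
                      as.character(seq_along(counts_1)),
                    p = p, fdr = fdr, fold = fc$fold,
                    direction = fc$direction,
                    significant = fdr < fdr_cut & !is.na(fc$fold) &
                      fc$fold > min_fold,
                    row.names = NULL)
  attr(res, "groups") <- labels
  class(res) <- c("abundance_calls", "data.frame")
  res
}

#' Convergent abundance changes across two species
#'
#' A corresponded cluster pair is convergent when both species' calls are
#' significant and the direction of change agrees. Directions are compared
#' positionally: each species' call table carries a `direction` naming one
#' of its two groups, and the group order given to the tests must be
#' analogous (e.g. uninseminated first, inseminated second in both species).
#'
#' @param calls_1,calls_2 `abundance_calls` data.frames for species 1 and 2.
#' @param correspondence data.frame with columns `source` (cluster in
#'   species 1) and `target` (cluster in species 2), e.g. from
#'   [correspondence_network()]; clusters without correspondence are skipped
#'   with a message.
#' @return data.frame `source`, `target`, `significant_1`, `significant_2`,
#'   `direction_1`, `direction_2`, `convergent`; the convergent cluster set
#'   is `unique(source[convergent])`.
#' @export
convergence_call <- function(calls_1, calls_2, correspondence) {
  g1 <- attr(calls_1, "groups"); g2 <- attr(calls_2, "groups")
  .assert(!is.null(g1) && !is.null(g2),
          "calls must carry their group labels (run the tests in this package)")
  skipped <- setdiff(calls_1$cluster, correspondence$source)
  if (length(skipped))
    message(sprintf("convergence_call: %d cluster(s) without correspondence skipped",
                    length(skipped)))
  out <- list()
  for (i in seq_len(nrow(correspondence))) {
    s <- correspondence$source[i]; t <- correspondence$target[i]
    r1 <- calls_1[calls_1$cluster == s, ]
    r2 <- calls_2[calls_2$cluster == t, ]
    if (nrow(r1) != 1L || nrow(r2) != 1L) next
    dir1 <- match(r1$direction, g1)   # positional: 1st or 2nd group higher
    dir2 <- match(r2$direction, g2)
    conv <- isTRUE(r1$significant) && isTRUE(r2$significant) &&
      !is.na(dir1) && !is.na(dir2) && dir1 == dir2
    out[[length(out) + 1L]] <- data.frame(
      source = s, target = t,
      significant_1 = r1$significant, significant_2 = r2$significant,
      direction_1 = r1$direction, direction_2 = r2$direction,
      convergent = conv)
  }
  if (!length(out))
    return(data.frame(source = character(0), target = character(0),
                      significant_1 = logical(0), significant_2 = logical(0),
                      direction_1 = character(0), direction_2 = character(0),
                      convergent = logical(0)))
  do.call(rbind, out)
}

#' Report a cluster fraction the way atlas headlines print it
#'
#' `100 * n_pass / n_total`, rounded half away from zero to `digits`
#' decimals. Headline fractions mix precisions (81.4% alongside 70%), so the
#' printed precision is a parameter.
#'
#' @param n_pass,n_total non-negative counts, `n_pass <= n_total`,
#'   `n_total > 0`.
#' @param digits decimal places (default 1).
#' @return list with `value` (the rounded percentage, numeric) and `label`
#'   (e.g. `"81.4%"`).
#' @export
report_fraction <- function(n_pass, n_total, digits = 1L) {
  .assert(n_total > 0, "report_fraction: n_total must be > 0")
  .assert(n_pass >= 0 && n_pass <= n_total,
          "report_fraction: need 0 <= n_pass <= n_total")
  value <- .round_half_up(100 * n_pass / n_total, digits)
  list(value = value,
       label = paste0(formatC(value, format = "f", digits = digits), "%"))
}
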