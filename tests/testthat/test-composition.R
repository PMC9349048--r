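# Relative abundances, compositional testing, convergence and reporting.

toy_table <- function() {
  cnt <- rbind(w1 = c(a = 30L, b = 70L),
               w2 = c(a = 30L, b = 70L),
               q1 = c(a = 10L, b = 90L),
               q2 = c(a = 20L, b = 80L))
  composition_table(cnt, c("worker", "worker", "queen", "queen"))
}

test_that("relative abundance in pooled and per-replicate modes", {
  tab <- toy_table()
  pooled <- relative_abundance(tab, "pooled")
  expect_equal(unname(pooled["worker", ]), c(30, 70))
  per <- relative_abundance(tab, "per_replicate")
  expect_equal(unname(per["q1", ]), c(10, 90))
  expect_equal(unname(rowSums(pooled)), rep(100, 2))
  expect_equal(unname(rowSums(per)), rep(100, 4))
  # identical replicates: pooled equals per-replicate rows
  expect_equal(unname(pooled["worker", ]), unname(per["w1", ]))
  expect_error(relative_abundance(tab, phenotypes = "gyne"), "unknown")
})

test_that("pooled mode is the replicate-total-weighted mean of per-replicate", {
  set.seed(2)
  cnt <- matrix(rpois(6 * 5, 40) + 1L, nrow = 6,
                dimnames = list(paste0("s", 1:6), paste0("c", 1:5)))
  tab <- composition_table(cnt, rep("w", 6))
  pooled <- relative_abundance(tab, "pooled")
  per <- relative_abundance(tab, "per_replicate")
  wts <- rowSums(cnt) / sum(cnt)
  expect_equal(unname(pooled["w", ]), unname(colSums(per * wts)))
})

test_that("radar normalization divides phenotype means by their maximum", {
  # one cluster with per-replicate means 2/4/1/3 (%) across four phenotypes
  cnt <- rbind(p1 = c(x = 2L, rest = 98L), p2 = c(x = 4L, rest = 96L),
               p3 = c(x = 1L, rest = 99L), p4 = c(x = 3L, rest = 97L))
  tab <- composition_table(cnt, c("w", "q", "g", "m"))
  rad <- radar_normalize(tab)
  expect_equal(unname(rad["x", c("w", "q", "g", "m")]),
               c(0.5, 1, 0.25, 0.75))
  expect_equal(max(rad["x", ]), 1)
  # scale invariance: multiplying all counts leaves the profile unchanged
  tab10 <- composition_table(cnt * 10L, c("w", "q", "g", "m"))
  expect_equal(radar_normalize(tab10), rad)
})

test_that("radar handles single-phenotype presence and absent clusters", {
  cnt <- rbind(p1 = c(only = 5L, rest = 95L, ghost = 0L),
               p2 = c(only = 0L, rest = 100L, ghost = 0L))
  tab <- composition_table(cnt, c("w", "q"))
  expect_warning(rad <- radar_normalize(tab), "ghost")
  expect_equal(unname(rad["only", ]), c(1, 0))
  expect_true(all(is.na(rad["ghost", ])))
})

test_that("fold change handles zeros the way absence is reported", {
  fc <- fold_change(c(k1 = 2, k2 = 3, k3 = 0, k4 = 0),
                    c(k1 = 1, k2 = 3, k3 = 6, k4 = 0),
                    labels = c("g", "w"))
  expect_equal(fc$fold, c(2, 1, Inf, NA))
  expect_identical(fc$direction, c("g", "equal", "w", NA))
  expect_true(fc$fold[3] > 1.3)   # infinite fold passes any finite gate
})

test_that("Fisher test equals the hypergeometric closed form", {
  # most-probable table -> p = 1
  expect_equal(crossatlas:::.fisher_p2(5, 5, 5, 5), 1)
  # (5,0; 0,5) -> 2 / choose(10, 5)
  expect_equal(crossatlas:::.fisher_p2(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:100) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c_ <- sample(0:15, 1); d <- sample(0:15, 1)
    if (a + b == 0 || c_ + d == 0 || a + c_ == 0 || b + d == 0) next
    expect_equal(crossatlas:::.fisher_p2(a, b, c_, d),
                 enum_fisher_p(a, b, c_, d), tolerance = 1e-10)
  }
})

test_that("fisher_abundance_test gates on FDR and fold", {
  c1 <- c(big = 400L, shifted = 60L, flat = 540L)
  c2 <- c(big = 400L, shifted = 20L, flat = 580L)
  res <- fisher_abundance_test(c1, c2, labels = c("gam", "wrk"))
  row <- res[res$cluster == "shifted", ]
  expect_true(row$significant)
  expect_identical(row$direction, "gam")
  expect_gt(row$fold, 1.3)
  expect_false(res$significant[res$cluster == "big"])
  expect_error(fisher_abundance_test(c(a = 0L), c(a = 5L)), "zero-total")
})

test_that("identical samples produce zero LRT statistics and no calls", {
  cnt <- matrix(rep(c(100L, 50L, 150L, 80L), each = 4), nrow = 4,
                dimnames = list(paste0("s", 1:4), paste0("c", 1:4)))
  tab <- composition_table(cnt, c("g1", "g1", "g2", "g2"))
  res <- dm_composition_test(tab, c("g1", "g2"))
  expect_lt(max(res$statistic, na.rm = TRUE), 1e-3)
  expect_false(any(res$significant))
  # compositional invariance: doubling one sample adds no effect
  cnt2 <- cnt; cnt2[1, ] <- cnt2[1, ] * 3L
  res2 <- dm_composition_test(composition_table(cnt2, c("g1", "g1", "g2", "g2")),
                              c("g1", "g2"))
  expect_false(any(res2$significant))
})

test_that("planted composition shifts are detected and the null is controlled", {
  set.seed(7)
  J <- 12
  draw <- function(p, conc = 300, cells = 1500)
    drop(rmultinom(1, cells, { g <- rgamma(J, conc * p); g / sum(g) }))
  base <- rep(1 / J, J)
  shifted <- base * ifelse(seq_len(J) %in% c(2, 9), 3, 1)
  shifted <- shifted / sum(shifted)
  cnt <- rbind(t(sapply(1:4, function(i) draw(base))),
               t(sapply(1:4, function(i) draw(shifted))))
  dimnames(cnt) <- list(paste0("s", 1:8), paste0("c", 1:J))
  tab <- composition_table(cnt, rep(c("u", "v"), each = 4))
  res <- dm_composition_test(tab, c("u", "v"))
  expect_true(all(c("c2", "c9") %in% res$cluster[res$significant]))
  expect_true(all(res$direction[res$cluster %in% c("c2", "c9")] == "v"))
  # small null batch: type-I proportion within twice the nominal level
  flagged <- 0L; tested <- 0L
  for (i in 1:12) {
    cntn <- t(sapply(1:8, function(k) draw(base)))
    dimnames(cntn) <- list(paste0("s", 1:8), paste0("c", 1:J))
    rn <- dm_composition_test(composition_table(cntn, rep(c("u", "v"), each = 4)),
                              c("u", "v"))
    flagged <- flagged + sum(rn$significant)
    tested <- tested + sum(!is.na(rn$p))
  }
  expect_lte(flagged / tested, 2 * 0.2)
})

test_that("auto reference picks the most stable ubiquitous cluster", {
  # every sample totals 1000, so "ref" has an exactly constant share (CV 0)
  cnt <- cbind(ref = rep(200L, 6),
               noisy = c(300L, 350L, 250L, 320L, 280L, 300L),
               other = c(500L, 450L, 550L, 480L, 520L, 500L))
  rownames(cnt) <- paste0("s", 1:6)
  tab <- composition_table(cnt, rep(c("g1", "g2"), each = 3))
  res <- dm_composition_test(tab, c("g1", "g2"))
  expect_identical(attr(res, "reference"), "ref")
  expect_true(is.na(res$p[res$cluster == "ref"]))
})

test_that("all-zero clusters are excluded with a warning", {
  cnt <- cbind(a = c(10L, 12L, 9L, 11L), dead = 0L, b = c(30L, 28L, 31L, 29L))
  rownames(cnt) <- paste0("s", 1:4)
  tab <- composition_table(cnt, rep(c("g1", "g2"), each = 2))
  expect_warning(res <- dm_composition_test(tab, c("g1", "g2")), "dead")
  expect_false("dead" %in% res$cluster)
})

test_that("convergence requires significance and agreeing directions", {
  mk_calls <- function(groups, sig, dir) {
    res <- data.frame(cluster = names(sig), significant = unname(sig),
                      direction = unname(dir))
    attr(res, "groups") <- groups
    class(res) <- c("abundance_calls", "data.frame")
    res
  }
  c1 <- mk_calls(c("gyne", "queen"),
                 c(k1 = TRUE, k2 = TRUE, k3 = TRUE, k4 = FALSE),
                 c(k1 = "queen", k2 = "queen", k3 = "gyne", k4 = "queen"))
  c2 <- mk_calls(c("worker", "gamergate"),
                 c(h1 = TRUE, h2 = TRUE, h3 = TRUE, h4 = TRUE),
                 c(h1 = "gamergate", h2 = "worker", h3 = "worker", h4 = "gamergate"))
  corr <- data.frame(source = c("k1", "k2", "k3", "k4"),
                     target = c("h1", "h2", "h3", "h4"))
  res <- suppressMessages(convergence_call(c1, c2, corr))
  expect_identical(res$convergent,
                   c(TRUE,    # both up in the reproductive state
                     FALSE,   # directions disagree
                     TRUE,    # both up in the first (uninseminated) group
                     FALSE))  # k4 not significant in species 1
})

test_that("report_fraction reproduces the printing convention", {
  expect_identical(report_fraction(35, 43)$label, "81.4%")
  expect_equal(report_fraction(35, 43)$value, 81.4)
  expect_identical(report_fraction(0, 43)$label, "0.0%")
  expect_identical(report_fraction(43, 43)$label, "100.0%")
  expect_identical(report_fraction(30, 43, digits = 0)$label, "70%")
  expect_error(report_fraction(1, 0), "n_total")
  expect_error(report_fraction(5, 4), "n_pass")
})
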