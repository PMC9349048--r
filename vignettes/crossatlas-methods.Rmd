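---
title: "crossatlas: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{crossatlas: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the procedures it
implements, the assumptions behind them, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the choices made
where the design was genuinely open. It states no empirical result that the
test suite or the acceptance script does not itself compute.

# The setting

Brain cell atlases of social insects compare single-nucleus transcriptomes
across adult phenotypes (for instance workers, queens, virgin queens and
males, sequenced as 5 + 4 + 4 + 4 pooled replicates) and across species.
After alignment and clustering — which this package deliberately does not
re-implement — the analyses that carry the biology are a chain of small,
bespoke decision rules: which reads and nuclei to keep, how to summarize a
cluster's expression, what counts as a marker or a differentially expressed
gene, which cluster in another species corresponds to a given cluster, and
whether a cell type's relative abundance really differs between phenotypes.
`crossatlas` implements that chain as tested, reusable functions, and ships
a generator that produces all inputs with known ground truth so each rule
can be validated end to end without any external download.

# Read filtering and nucleus QC

`filter_alignments()` applies three rules, in order, attributing each
discarded read to the first rule it fails:

1. reads reported at multiple genomic positions (NH tag > 1, or the same
   read id appearing in more than one record) are dropped;
2. spliced reads with any single alignment gap longer than 50 kb are
   dropped — the rule is applied **per gap**, not to the total spliced
   span, because the stated motivation (introns longer than 50 kb are
   vanishingly rare) is a property of individual introns;
3. spliced reads whose intron terminal dinucleotides are not GT/AG, GC/AG
   or AT/AC are dropped. Because library strandedness is not guaranteed,
   the motif is accepted in either genomic orientation (equivalently:
   CT/AC, CT/GC, GT/AT on the forward strand).

A chromosome referenced by a spliced record but absent from the genome, or
a gap running past a chromosome end, is a hard error naming the record:
silent skipping would bias the filter.

`qc_nuclei()` keeps nuclei with 200–2,000 expressed genes (a gene is
expressed at UMI ≥ 1) and a mitochondrial UMI fraction of at most 1%.
Bounds are inclusive: the stated rule discards *fewer than* 200, *more
than* 2,000, *more than* 1%. Mitochondrial genes are supplied as an
explicit list — no name-pattern magic — so the rule ports across species.
QC only subsets; retained counts are never modified.

# Expression summaries, markers and DEGs

`cluster_expression()` computes, per cluster and gene, the mean over member
nuclei of the within-cell UMI fraction, scaled by 10⁶. The within-cell
share is treated as a fraction in [0, 1]; reading it as a 0–100 percentage
would multiply every value by 100 and cannot change any correlation,
ranking or dendrogram downstream, so the choice is cosmetic and recorded
here once.

Markers (`find_markers()`) and DEGs (`find_degs()`) use the Wilcoxon
rank-sum test on CP10K values, with a normal approximation including the
tie correction and a 0.5 continuity correction. The hurdle-model machinery
of MAST is out of scope by design: downstream logic consumes only the gate
triple (FDR < 0.05, fold change > 1.25, expressed in > 20% of up-group
cells), and the rank-sum test reproduces that decision surface with far
fewer assumptions. The marker pre-filters follow the Seurat-3 convention
(min.pct = 0.25, natural-log fold change ≥ 0.25 on mean CP10K + 1,
positive only); the log convention is natural log and is stated in the
function documentation and column name (`avg_logfc`). The approximation is
validated in the tests against an exhaustive-permutation oracle on a
six-cell example (agreement within 10%), and against planted and null
simulations (≥ 95% of detectable planted markers recovered; ≤ 2× the
nominal FDR flagged under a global null). A planted marker whose baseline
expression leaves it below min.pct even after fold-10 up-weighting is
excluded by the gate itself, for any implementation; recovery is therefore
measured among markers that meet the gate's expression precondition, with
an unconditional floor asserted as well.

`correlation_dendrogram()` ranks genes by mean expression across the
clusters of interest (ties broken lexicographically by gene id, for
determinism), keeps the top 8,000 by default, computes 1 − Pearson
correlation between cluster profiles and agglomerates with classic Ward
("ward.D") linkage. Branch support is the plain bootstrap proportion over
gene resamples — the multiscale AU correction of pvclust is out of scope,
and plain proportions are both simpler and more conservative for the
sibling-pair statements the analyses make.

# Orthology and GO

`reciprocal_best_hits()` reduces multiple HSPs to the maximum bit score per
gene pair (standard RBH practice), takes each gene's best-scoring partner,
and keeps a pair when the choice is mutual. An exact bit-score tie for a
gene's best hit disqualifies that gene entirely rather than breaking the
tie arbitrarily: orthology calls must not depend on row order. E-value
thresholds are applied upstream by the aligner and are not re-checked.

`transfer_go()` annotates each target gene from its orthologue in the
highest-priority reference species in which a pair exists (the stated
priority being evolutionary proximity). When no priority species has a
pair, an optional best-hit fallback table supplies the terms. A gene whose
orthologue exists but carries no GO terms stays empty — the fallback fires
only when *all priorities miss*, which follows the stated rule's structure;
the alternative reading (fallback whenever the term set is empty) is noted
as plausible but not chosen.

`go_enrichment()` builds the background exactly as stated: all genes with
mean cluster-level expression above CP10K 1 across the clusters of
interest, minus the up-regulated DEGs themselves. The test is the one-sided
(over-representation) Fisher's exact test on the four listed counts —
"enriched" names an upper tail; a two-sided option is exposed. Terms are
tested independently, without GO-graph propagation. Gates: FDR < 0.05 and
at least 2 DEGs in the term.

# Pseudo-cells and mean-AUROC correspondence

Sparsity, not biology, dominates single-nucleus profiles, so correspondence
is computed on pseudo-cells: within each cluster, cells are shuffled
(seeded) and partitioned into disjoint groups of exactly 10; each group's
UMIs are summed by gene and CP10K-normalized. Remainders are dropped and
counted rather than padded — group size stays exactly 10 as stated.
Profiles are then z-transformed per gene, `z = (x − m)/s.d.`, with the
**population** standard deviation across all pseudo-cells of the dataset
(zero-variance genes get z = 0; both conventions are recorded in the object
metadata). The gene axis is restricted to orthologous genes that are
cluster markers in at least one of the two compared datasets — the subset
that maximizes between-cluster contrast.

A target pseudo-cell's *vote* for a source cluster is its mean Pearson
correlation with that cluster's pseudo-cells; the AUROC for a cluster pair
is the Mann–Whitney probability that a member of the candidate target
cluster out-votes a non-member, ties counted one half, computed by the
midrank formula. Between-dataset scores average the two voting directions;
within-dataset scores are computed identically with each pseudo-cell's
self-correlation excluded from its own vote (otherwise the diagonal
trivially inflates). The original neighbour-voting framework
rank-normalizes votes and applies degree corrections; because the AUROC is
invariant under any strictly monotone transform of the votes — a property
the tests verify — rank-normalization is a no-op for the score, and the
simpler contract is used. Whether the original tool also included
within-dataset cells in the voting pool for between-dataset scores is not
documented; here the voting pool is always the source dataset's
pseudo-cells, a choice the `auroc_pair(source, target)` API makes explicit
rather than hiding behind a flag, without any claim of bit-for-bit
equality with the original tool.

Cluster dendrograms use Ward linkage on 1 − AUROC (clamped at 0).
Correspondence edges require AUROC > 0.80 (strict), with a second edge when
the runner-up also clears 0.80 and trails the top hit by less than 0.05
(strict on both sides).

# Compositional differential abundance

Cell-type counts per sample live on a simplex: when one cluster expands,
every other share must shrink. The reference Bayesian tool models this with
a hierarchical Dirichlet-multinomial and spike-and-slab inclusion; its HMC
sampler is out of scope, and the package substitutes a maximum-likelihood
Dirichlet-multinomial likelihood-ratio test with the *same decision
surface*: sample `i` in group `g` has counts
`y_i ~ DM(n_i, α_g)` with `log α_{g,j} = β0_j + β_{g,j}`, the reference
cluster's group effects fixed at zero, a per-cluster LRT of zero group
effect (df = groups − 1), Benjamini–Hochberg across tested clusters, and
significance requiring both `fdr < level` (0.2 within species, 0.1 between)
and a pooled-relative-abundance fold change above the gate (1.3 within, 2
between). The automatic reference is the cluster detected in every sample
with the smallest coefficient of variation of per-replicate relative
abundance — the same "most stable ubiquitous cluster" principle as the
reference tool's automatic selection.

Numerical choices that matter: parameters are optimized with L-BFGS-B under
box bounds of ±25 on the log scale (unbounded quasi-Newton steps can push
`Σα` to overflow, where the digamma gradients go undefined); the starting
point is moment-based (concentration from the across-sample variance of
proportions, clamped to [2, 10⁴]; effects from group log-ratio contrasts
against the reference); restricted fits are warm-started from the full fit;
and if a restricted fit ever finds a better mode than the running full fit,
the full model is refit from that mode (statistics are clamped at 0).
Identical samples across groups yield statistics that are numerically zero,
and multiplying one sample's counts by a constant creates no effect — both
are asserted in the tests.

Fold changes are computed on pooled (not mean-of-replicate) relative
abundances, larger over smaller, with the direction naming the higher
group. A cluster entirely absent on one side reports an *infinite* fold
rather than a pseudo-counted ratio: the analyses treat complete absence as
a qualitative difference, and an infinite fold passes any finite gate while
remaining visibly distinct in output. Absent on both sides is undefined
(`NA`). How the original ">1.3-fold" was computed for one-sided absences is
not stated anywhere; this convention is flagged as a package choice.

The pooled cross-species/caste test (`fisher_abundance_test()`) uses a
two-sided Fisher's exact test per cluster, implemented by direct
hypergeometric enumeration (sum of all margin-fixed tables no more probable
than the observed one, with the standard 1 + 1e-7 relative tolerance) so it
can be checked against an independent `lchoose`-based oracle to 1e-10 —
gates FDR < 0.001 and fold > 1.3. `convergence_call()` marks a corresponded
cluster pair convergent when both species' calls are significant and the
direction of change agrees positionally (the group orders passed to the two
tests must be analogous, e.g. uninseminated first).

`report_fraction()` reproduces the headline reporting arithmetic:
`100 × n/N`, rounded half away from zero. Published headlines mix
precisions (81.4% alongside 70% for 30/43, which is 69.8% at one decimal),
so the printed precision is an explicit `digits` argument rather than a
fixed rule.

# The synthetic world

`simulate_atlas()` states one world and keeps it fixed:

* **Design**: four phenotypes with 5/4/4/4 replicates by default, 43
  clusters, ~12,000 nuclear genes plus 13 mitochondrial genes, ~12,000
  cells per replicate — the scale of the motivating atlas. Tests and
  examples pass smaller configs explicitly and say so.
* **Composition**: a per-phenotype expected composition (base simplex ×
  planted multipliers, renormalized), jittered per replicate by a Dirichlet
  with concentration 200 — enough overdispersion that a naive binomial test
  would be anticonservative, which is precisely what the DM test must
  handle.
* **Expression**: per-gene baseline rates are log-normal (sdlog 1.5, a
  heavy-tailed bulk of low expressors with a minority of high ones); each
  cluster up-weights its own disjoint marker set by `marker_fold` (default
  8; markers are drawn uniformly over genes, so some markers are
  intrinsically rare); mitochondrial genes carry a fixed 0.5% of each
  cell's expected UMIs (under the 1% QC gate). Per-cell totals are
  log-normal around 1,500 UMIs (sdlog 0.35) and gene counts are multinomial
  conditional on the total — which makes CP10K exact by construction.
* **Two species**: a configurable fraction (default 0.8) of genes are
  one-to-one orthologues; orthologous genes share baseline rates up to
  log-normal noise (sdlog 0.15) and share marker membership, so homologous
  clusters are the ground-truth correspondence.
* **Reads**: `simulate_sam()` plants junction motifs *into the genome
  sequence* at each read's junction, so the filter must read them back from
  the FASTA; long-gap reads carry canonical motifs (they must fail on
  length alone) and non-canonical reads use AA/AA (non-canonical in both
  orientations).

What the generator does **not** emulate — and hence what a green test does
not establish: no doublets, no ambient RNA, no batch structure (clustering
is consumed as given labels, so integration is never exercised), no
gene-gene correlation beyond the shared programs, no length or GC bias, and
cluster programs that differ far more cleanly than real cell subtypes do.
Perfect AUROC recovery on synthetic data is a correctness check of the
machinery, not a promise about noisy real atlases.

# Known limitations

* The DM-LRT substitutes the reference tool's Bayesian inclusion
  probabilities with frequentist p-values; the binary calls target the same
  decision surface, but posterior quantities are not reproduced.
* `dm_composition_test()` accepts exactly two groups — every contrast in
  the motivating analyses is pairwise, and the fold/direction half of the
  decision surface is only defined for two groups.
* The rank-sum normal approximation is inaccurate for extremely small
  groups (< ~5 cells); clusters under 3 cells are skipped with a warning.
* Bootstrap branch support is a proportion, not an approximately unbiased
  (AU) p-value; values are comparable within a tree, not across methods.
* The CLI covers the pipeline driver, the simulator and the read filter;
  all other operations are exported R functions rather than subcommands.
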