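---
title: "Methods: from peripheral-blood single cells to imatinib-response signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from peripheral-blood single cells to imatinib-response signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmlsig)
```

`cmlsig` chains five analysis stages: QC/normalization of single-cell UMI
counts, clustering and marker detection, projection of query cells onto a
reference map, Pearson-correlation signature scoring of bulk cohorts with
ROC evaluation, and permutation/Fisher statistics for cell-cell interaction
and compositional enrichment. This vignette explains each model, the
parameters that matter, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## QC and normalization

Cells are retained when they have at least `min_genes_per_cell` detected
genes (default 200) and a mitochondrial UMI fraction of at most
`max_mito_fraction` (default 0.05); genes are retained when detected in at
least `min_cells_per_gene` cells (default 3). Mitochondrial genes are
recognized purely by the `MT-` name prefix, the 10x convention. All
boundaries are inclusive for retention: a cell with exactly 200 detected
genes or exactly 5% mitochondrial UMIs is kept. Descriptions of such
filters are often ambiguous between strict and inclusive readings; we fix
the inclusive convention because it is the one under which a "cells with at
least 200 detected genes" summary of the retained population is exactly
true. Filters are idempotent and preserve cell/gene order, so re-applying
QC is a no-op.

Normalization is the standard depth normalization
$\log(1 + c_{ij}/T_i \times 10^4)$ with natural log, per-cell total $T_i$
and scale factor $10^4$ (configurable). It is invariant to per-cell depth
rescaling and leaves all-zero cells as all-zero rows. For PCA, genes are
centered and scaled to unit variance with scaled values clipped at ±10;
clipping prevents a handful of outlier cells from dominating a component.
Zero-variance genes get scale 1 so they contribute exactly 0 after
centering.

## Clustering and markers

PCA is computed by SVD of the centered/scaled matrix; component variances
are the covariance eigenvalues and are non-increasing by construction.
Clustering builds an exact k-nearest-neighbor graph (k = 20, Euclidean in
PC space) and partitions it by Louvain modularity optimization. The
`resolution` parameter trades cluster count against cluster size and is
deliberately config-exposed rather than asserted: no single value is
canonical, and the package's tests validate recovery of planted clusters
rather than a particular resolution. Community detection is randomized in
general, so the search runs under a caller-supplied seed and is
reproducible bit-for-bit.

Markers are detected per cluster (or between two explicit cell groups) by
a two-sided Wilcoxon rank-sum test on normalized expression, restricted to
genes expressed in at least `min_pct` (default 0.10) of either group, with
Benjamini-Hochberg correction across the tested genes. The log2 fold
change uses depth-normalized (expm1-transformed) group means with
pseudocount 1 — the common single-cell convention that avoids log-of-zero
and keeps fold changes comparable across expression levels. The canonical
marker gate downstream is FDR < 0.05 and fold change > 2. Groups with
fewer than 3 cells are rejected: a rank test on one or two observations is
meaningless.

Module scores are the mean expression of a gene set minus the mean of
control genes drawn, per set gene, from the same average-expression bin
(24 equal-occupancy bins, 100 controls per gene, sampled without
replacement under a seed). Binned controls remove the component of the
score that merely tracks expression magnitude; on a constant matrix every
score is exactly 0. Cell-cycle scoring applies this to bundled S (43
genes) and G2/M (54 genes) human gene lists and assigns the
higher-scoring phase when either score is positive, G1 otherwise.

## Reference projection

To place query cells onto a reference map, the 2,000 most variable genes
(variance of log-normalized expression in the *reference*, computed over
the reference∩query gene intersection, clamped to the intersection size)
define the feature space; PCA (top 30 PCs) is fitted on the reference
only; and query cells are transformed with the reference's centering,
scaling and loadings — never their own statistics, because the reference
defines the coordinate system and query-side scaling would let the query's
composition distort it. Each query cell's 5 nearest reference cells under
Euclidean distance in PC space are its anchors; nearest-neighbor search is
exact, with ties broken by reference cell index so the projection is
deterministic and invariant to query order. The projection is rendered as
a Gaussian kernel density over anchor embedding coordinates (anchors
counted with multiplicity), per-axis Scott bandwidth $\sigma n^{-1/6}$, on
a 200×200 grid padded 4 bandwidths beyond the embedding extent and
normalized so the Riemann sum is exactly 1. A degenerate axis (all anchors
at one coordinate) falls back to a small positive bandwidth rather than a
zero division.

## Signature classifier

A cluster signature is its top 50 significant markers (ordered by FDR,
then fold change) with the in-cluster mean normalized expression as the
representative value. A bulk patient is scored by the Pearson correlation
between the signature values and the patient's log2 expression over the
shared genes (at least 3 required); the cohort is taken as provided, with
no re-normalization, since bulk cohorts of this kind are already
RMA-processed and log2-scaled upstream. Zero-variance patient profiles
yield `NA` scores that are excluded pairwise with a warning.

Classes are compared by Welch's unequal-variance t-test — the robust
default when only "unpaired t test" is specified. The ROC takes
non-responders as the positive class with higher scores predicting
non-response; AUC is the Mann-Whitney probability with ties counted ½, and
its confidence interval uses the DeLong placement-variance method, with an
optional stratified bootstrap (2,000 seeded resamples) for sensitivity
bands at fixed specificity. Two combination rules for multiple signatures
are provided: averaging the per-signature correlation scores (default) and
scoring the union gene list with duplicate values averaged. Both are
natural readings of "integrating" two cluster signatures; neither is
privileged, and on planted data they agree closely. A max-value probe
collapse utility (`collapse_probes`) is included for microarray cohorts;
platform annotation files are out of scope.

## Interaction and enrichment statistics

The ligand-receptor score between clusters A and B is the arithmetic mean
of (mean ligand expression in A, mean receptor expression in B) on
normalized data — the literal "average expression of the pair in the two
clusters". A pair is tested only if ligand and receptor are each expressed
(count > 0) in strictly more than 30% of their cluster's cells. The null
is built by globally shuffling *all* cells' cluster labels (not only the
two clusters involved), matching a null in which cluster identity carries
no expression information; the empirical p is the one-sided upper-tail
rank of the observed score among `n_perm = 1000` permuted scores with
floor 1/n_perm — a finite permutation run can never honestly report p = 0.
One-sided is the appropriate tail because only elevated interaction is of
interest; this choice is deliberate where a rank-based description leaves
the tail ambiguous.

Fisher's exact test on 2×2 tables uses the classic two-sided convention
(sum of hypergeometric point probabilities not exceeding the observed
one). The enrichment score of a sample within a cluster is the log10 odds
ratio with Haldane correction (0.5 added to every cell) applied always,
not only at zeros, so scores are finite and mutually comparable across a
heatmap; the raw cross-product OR is reported alongside. BH correction
runs across all (cluster, sample) pairs.

## The synthetic-data generator

Counts are negative-binomial (gamma-Poisson) with per-gene dispersion 0.3,
a typical UMI over-dispersion, and one mean parameter per gene: base mean
`base_mean` everywhere, elevated by `marker_fold_change` for a cluster's
planted markers inside that cluster. Mitochondrial genes (named `MT-…`)
are scaled per cell so the expected mitochondrial fraction equals a
uniform draw from `mito_fraction_range`; cell-cycle programs can be
planted as elevated expression of the bundled S/G2M lists in designated
cells. Reference/query pairs are independent draws from the same
per-cluster model, so each query cell has a known cluster of origin.

Bulk cohorts plant the *statistic the classifier uses* directly: a
patient's profile over the signature genes is
$x = \bar{x} + a\,(r\,u + \sqrt{1-r^2}\,w)$ with $u$ the standardized
centered signature and $w$ orthogonal standardized noise, so the Pearson
correlation with the signature equals $r$ exactly (to machine precision).
Per-patient $r$ is drawn from class-shifted normals with common SD
`score_sd` (0.08) around a base correlation of 0.25, the non-responder
mean elevated by `effect_size_d × score_sd`. Because the score
distributions are exactly normal with equal variance, the downstream AUC
has the closed form $\Phi(d/\sqrt{2})$ — at the default d = 2,
$\Phi(\sqrt 2) \approx 0.921$ — which turns classifier validation into a
parameter-recovery test with a known answer. An additive
$\alpha\cdot s + \varepsilon$ construction would plant the same effect
only approximately (the realized correlation would inherit noise from
$\varepsilon$); planting $r$ itself removes that slack without changing
what is being tested.

What the generator does **not** emulate: batch effects, doublets, ambient
RNA, library-size heterogeneity beyond the NB model, gene-gene
correlation beyond the planted structure, and any BCR-ABL fusion
signal. Passing tests therefore demonstrate correctness of the
statistical machinery under its stated model, not robustness to the
artifacts of real 10x data.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at deliberately moderate
sizes chosen so Monte-Carlo error is small relative to every asserted
band: marker and cohort recovery at 100 cells or patients per group over
10–20 seeds, projection purity at 3×100 reference cells over 10 seeds,
null calibration at 400–600 permutation tests of 1,000 shuffles each and
500–800 rank-sum tests. Oracle equivalences (AUC vs exhaustive pair
counting, Fisher p vs hypergeometric enumeration, k-NN vs brute-force
ranking, Wilcoxon vs exhaustive 5v5 enumeration) are exact to numerical
tolerance. Determinism is end-to-end: every stochastic step (generation,
community detection, control-gene sampling, permutation, bootstrap) takes
an explicit seed, and generators restore the caller's RNG state.

## Known limitations

- Louvain partitions depend on the seed for near-degenerate graphs; only
  seeded determinism and planted-structure recovery are guaranteed.
- The Wilcoxon marker test uses the exact distribution only for small
  tie-free groups (delegating to the standard implementation); large
  groups use the normal approximation with continuity correction, which
  is mildly conservative under heavy ties.
- The projection assumes the reference spans the query's states; cells
  from states absent in the reference still receive anchors (their
  nearest, however distant). Anchor distances should be inspected when
  that risk exists.
- 2-D embeddings are visualization plumbing: cluster geometry in the
  embedding is never asserted, and any seeded embedding may be
  substituted.
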