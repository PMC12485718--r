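---
title: "Methods: correspondence, staging and QC for AP-gastruloid scRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correspondence, staging and QC for AP-gastruloid scRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaxis)
```

This vignette is the package's own account of the methods it implements:
the models and their assumptions, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where several readings were defensible.

## The analysis problem

An anteroposterior-patterned gastruloid profiled by droplet scRNA-seq
yields a genes × cells UMI matrix whose clusters must be (i) cleaned of
low-quality cells and doublets, (ii) matched to cell types of in vivo
embryo atlases, and (iii) placed on a developmental time axis. The package
treats each step as a defined, testable computation, and ships a simulator
that plants the truth each step is supposed to recover.

## Quality control

`compute_cell_qc()` summarises each cell by UMI total, detected genes, and
the percentage of UMIs on mitochondrial (chromosome MT) and ribosomal
(RPS/RPL) genes. `apply_cell_filters()` applies two conjunctive passes:

* pass 1 — fewer than 1,000 UMIs or fewer than 500 detected genes;
* pass 2 — fewer than 5,000 UMIs, the top 0.1% of cells by UMI total,
  doublet score over 0.2, MT% over 10, or Ribo% over 40.

All wordings are strict inequalities, so boundary cells (exactly 5,000
UMIs, score exactly 0.2) are retained. Two readings of the "top 0.1%"
rule exist — a cell-count rule or a percentile-value threshold; we read it
as counting cells and remove the `ceiling(0.001 * N)` highest-UMI cells,
because the phrase quantifies over "the total cells". `N` is the
population entering pass 2, i.e. the pass-1 survivors, matching the order
in which the two filter blocks are described; ties are resolved by
removing later cell ids first so the result is deterministic. Gene-level
retention happens in two named stages: `"primary"` (chromosomes 1–22, X,
Y, MT only, applied to the raw matrix — we apply the pass-1 cell filters
after this retention, again following the description order) and
`"embedding"` (protein-coding + lincRNA, sex chromosomes dropped).

Whole-cluster doublet removal is, in practice, a manual judgement over the
per-cluster score distribution; `flag_doublet_clusters()` reconstructs it
as a rule — flag clusters whose mean score exceeds twice the median of the
per-cluster means. The factor is conservative and user-overridable; with
very few clusters the median itself can be contaminated by doublet-heavy
clusters, which is a documented limitation of any automatic version of
this judgement.

## Normalization, feature selection, embedding

`lognormalize()` computes `log(1 + 10^4 * count / total)` per cell, so
`sum(expm1(values))` is exactly 10,000 per cell — an invariant the tests
assert at 1e-6 relative tolerance. `select_hvg()` ranks genes by
standardized dispersion: a loess trend (span 0.3, degree 2) of log10
variance on log10 mean assigns each gene an expected variance, and the
ratio observed/expected is ranked. The source pipeline names only "most
highly variable genes"; this trend-standardized dispersion is the default
behaviour of the toolkit that pipeline used, which is why we adopt it. At
fewer than ten usable genes the trend is unidentifiable and a plain
variance/mean ratio is substituted.

The cell-cycle index is likewise delegated to an external convention in
the source pipeline; `module_score()` reconstructs it as a bin-matched
module score (25 equal-frequency expression bins, 100 control genes per
set gene, seeded sampling). Scoring a gene set against bin-matched
controls is unbiased only when the set does not dominate its own bins, so
the function is intended for sets that are small relative to the gene
universe; precomputed scores can be passed directly to
`scale_and_regress()` instead.

`scale_and_regress()` regresses each gene on the covariates by OLS
(intercept included) and standardizes the residuals — regress-then-scale,
matching the "scale, regressing out" order of the stated toolkit.
Residual–covariate correlations are zero to 1e-10 by construction.
`pca_embed()` uses an exact SVD of the centred cells × genes matrix (no
randomized approximation is needed at these sizes) with a deterministic
sign convention: each loading vector is oriented so its largest-magnitude
entry is positive. `neighbor_graph_cluster()` builds a kNN graph and
delegates to igraph's Louvain implementation (resolution 1 by default);
community detection is not this package's contribution, so it is bought,
not built. Note that modularity optimization may split one geometric
cluster into several communities when the graph is sparse relative to the
cluster size — the granularity is a property of k and the resolution, not
an error.

## Reciprocal NNLS correspondence

For target cluster *a* in dataset A, `select_genes_for_target()` takes the
union of the `n_expr = 1500` genes with the highest mean log-normalized
expression in *a* and the `n_spec = 1500` genes with the highest
specificity. "Most highly expressed" could be read on raw or normalized
means; we rank on mean log-normalized values because normalization
precedes averaging in the pipeline's own order. Specificity is the
target mean divided by the across-cluster mean (+1e-8), the conventional
specificity ratio in the atlas-comparison literature; genes absent from
the target are excluded from that ranking.

`nnls_fit()` solves the non-negative least squares problem with a free
intercept by augmenting the design with +1 and −1 constant columns inside
a single Lawson–Hanson solve; the intercept equation is honoured without
constraining its sign, and one canonical solver covers both directions.
The solver is `pracma::lsqnonneg`; its correctness here is established
against an exhaustive active-set oracle (all 2^p sign patterns, p ≤ 8) in
the test suite rather than taken on trust.

`correspondence_matrix()` fits every A-target against all B profiles and
vice versa, then combines `beta_ab[a, b]` with `beta_ba[b, a]` — the only
pairing for which "reciprocal" is well-defined — as
`2 * (beta_ab + 0.01) * (beta_ba + 0.01)`. Rows of the combined matrix are
divided by their maxima for display ("row-scaled"); z-scaling is a
plausible alternative reading and can be applied by the user to
`$combined` directly. Pseudobulk downsampling (defaults exposed, e.g. 200
vs 500 cells per cluster) is a single seeded draw per cluster, in sorted
cluster-label order, without replacement; we downsample after per-cell
normalization because normalization is per-cell and unaffected by which
cells are kept. Cross-species comparisons collapse the query matrix onto
homolog ids with `map_homologs()`, which sums relative counts over a
possibly many-to-many table and re-normalizes — exactly equivalent to
collapsing raw counts and re-normalizing over the mapped universe.

## kNN staging and neighbourhood composition

The staging space in the source study came from an anchor-corrected
integration; that correction is a third-party algorithm and out of scope
here, so `joint_embed()` provides a plain joint PCA over shared HVGs (the
query cells participate in the fit, consistent with an "integrated"
space), and externally corrected coordinates can be passed straight to
`knn_reference_composition()`. The staging statistic itself — not the
batch correction — is the defined computation.

Staging finds, for each query cell, the k = 15 nearest reference cells
*within each embryonic stage*; the description does not say how the
per-stage sets are merged, so the default pools the per-stage candidates
and keeps the k globally nearest (`per_stage_pool`), with plain global kNN
(`global`, used with k = 20 for cell-type composition) exposed as the
alternative; with a single-stage reference the two modes coincide exactly,
which the tests assert. Distances are Euclidean in PC space, ties broken
by reference row order. `aggregate_composition()` averages the per-cell
fraction vectors per group, reports the modal label (ties to the first
label in order) and the five most abundant labels per group.

## The synthetic-data generator

`generate_dataset()` draws counts negative-binomially (one shared
dispersion, default 0.5) around
`lambda = libsize * softmax(base + type_effect * markers +
stage_effect * stage * gradient + batch)`: cell types are disjoint
marker-gene blocks shifted by `type_effect` (default 2) in log-mean; the
stage signal moves expression monotonically along one fixed random gene
direction (default `stage_effect` 1; the staging experiments use 2, the
value at which the planted gradient clearly dominates the embedding);
library sizes are log-normal (median 20,000 UMIs, log-sd 0.35, typical of
modern droplet chemistry); doublets are literal sums of two freshly drawn
singlet profiles from two distinct types and carry simulated doublet
scores (means 0.5 vs 0.05, sd 0.05, truncated to [0, 1]) chosen so the
0.2 threshold separates the populations — scores are simulated because
their computation belongs to an external tool. Mitochondrial and ribosomal
genes are excluded from marker and gradient roles so QC fractions stay
comparable across types. A single RNG stream is seeded from the simulation spec;
paired datasets derive two sub-seeds by fixed offsets and apply
independent per-gene batch shifts (sd `batch_effect`, default 0.3).

What the generator does **not** emulate: gene–gene correlation beyond the
planted type/stage/batch structure, ambient RNA, UMI saturation, cell-type
abundance imbalance, or empirically calibrated mean–variance trends.
Passing the planted-truth tests therefore demonstrates that the
implementations compute what they claim on data with the assumed
structure — not that the statistics are robust to every artefact of real
tissue data.

## Problem sizes and verification design

The verification experiments are sized for quick, repeated execution:
correspondence recovery uses 10 shared types × 200 cells × 2,000 genes
across five seeds (recovery is 10/10 at `type_effect = 2` and collapses to
chance as the effect vanishes); staging uses a 4-stage reference of 500
cells per stage with 50 held-out query cells per stage (k = 15,
`per_stage_pool`), checked bit-identically against an all-pairs
brute-force implementation; the NNLS oracle covers 100 random instances
with up to 8 clusters and 50 genes; the QC boundary fixture plants 1,000
cells straddling every threshold. `scripts/acceptance.R` re-runs all of
these from scratch under a caller-supplied seed. The staging experiment
sets `doublet_rate = 0` so the per-stage reference counts are exact by
construction.

## Known limitations

* No batch-effect correction: when two datasets differ by more than the
  simulator's additive shift (protocol, chemistry, species), the joint PCA
  will partly embed the batch, and an externally corrected space should be
  supplied.
* The correspondence statistic has no significance calibration (none is
  defined for it); row-scaled values are relative within a target row.
* `flag_doublet_clusters()` assumes doublet-enriched clusters are a
  minority of clusters.
* The qPCR transform uses `2^-dCt` relative expression before z-scoring;
  a linear-ratio alternative would change z-scores because z-scoring is
  only invariant to affine per-row transforms. The chosen transform is the
  field's standard reading of "normalized to the housekeeping gene".
* Pearson + Benjamini–Hochberg at 0.05 defines "significant" PC1
  correlation; the analysed study did not state its criterion, so the
  conventional one is used and reported explicitly in the output columns.
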