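---
title: "Selecting major cell groups: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting major cell groups: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Graph-based clustering of single-cell RNA-seq depends on two parameters
that interact with everything downstream: the number of top principal
components (nPC) that define the similarity space, and the resolution that
(indirectly) sets the number of groups k. This package treats the choice
of (nPC, k) as a model-order selection problem. The premise: at the k
where a *major*, well-separated population splits off, the partition moves
sharply away from what uniform noise could produce, and this is visible as
a large increase of the gap statistic from k − 1 to k. Sweeping nPC and
tabulating these increases localizes the (nPC, k) combinations worth
evaluating; the expensive part — marker-gene detection and separability
scoring — is then run only on those few candidates.

For a partition of cells into groups r = 1..k in the top-nPC space, the
within-group dispersion is

  W = Σ_r D_r / (2 n_r),

with D_r the sum of Euclidean distances over all ordered within-group
pairs and n_r the group size, and the gap statistic is

  Gap(nPC, k) = (1/B) Σ_b log W*_b − log W,

where each W*_b comes from n cells sampled uniformly in the axis-aligned
bounding box of the observed top-nPC coordinates and partitioned into k
groups. Note the original gap-statistic k-selection rule (first local
optimum) is *not* used; only the increases M(nPC, k) = Gap(nPC, k) −
Gap(nPC, k − 1) enter the candidate selection, because the goal is major
groups, not the finest statistically defensible k.

### Nested partitions

Rather than re-clustering at every k, one fine partition per nPC (at least
k_max groups; the resolution is raised from 1.0 in 0.2 steps until this
holds, capped at 5.0) is coarsened by iteratively merging the two groups
with the closest centroids (unweighted means of member cells, recomputed
after each merge; distance ties broken by the lowest id pair). This mirrors
the fine-to-coarse process by which subtypes aggregate into types and
guarantees the k-series is nested, so gap increases compare a partition
with its own refinement. Modularity-based community detection at the
initial resolution over-segments large homogeneous populations — this is
expected and harmless, since merging restores them; what matters (and what
the tests assert) is that well-separated populations are never mixed
within a community.

### Candidate selection and evaluation

Increases at or below mean + 1·sd (moments over all finite entries of M;
sample sd) are discarded; per column k the largest surviving entry is
kept; the kept entries, sorted by decreasing increase, are accepted
greedily when both nPC and k strictly exceed every accepted value. The
rationale for the strict-increase rule: additional groups (larger k)
should be credited only when they come from additional signal directions
(larger nPC). Each accepted candidate is evaluated by one-vs-rest
Wilcoxon DE genes and per-group CART trees; the final classification
error is the mean over nsplit = 5..15 of Σ_groups (training relative
error × group cell fraction). Training (resubstitution) error is used
deliberately: the question is whether the groups *can* be separated by
their own DE genes at bounded tree complexity, not out-of-sample accuracy.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `r_ini` | 1.5 | resolution for the k_max heuristic; > 1 so both ends of the nPC range over-segment |
| `npc_span` | 20 | nPC_max − nPC_min; widens the search, rarely changes the best set |
| `r_start`, `r_step`, `r_cap` | 1.0, 0.2, 5.0 | resolution schedule for the initial fine partition |
| `gap_B` | 100 | uniform reference draws per gap value; Monte-Carlo error ∝ 1/√B |
| `min_genes`, `max_mito_frac` | 200, 0.05 | cell filter: ≥ 200 detected genes, ≤ 5% mitochondrial UMI (both inclusive) |
| `min_logfc`, `min_pct`, `max_padj` | 0.25, 0.1, 0.05 | DE thresholds (natural-log fold change; expressing fraction; Bonferroni-adjusted p) |
| `nsplit_range` | 5–15 | tree split counts averaged into the final error |
| `knn`, `snn_prune` | 20, 1/15 | neighbor count and Jaccard pruning of the SNN graph |
| `min_cells_recurse` | 100 | smallest input for a run / recursion into a group |

Sample (n − 1) standard deviations are used throughout scaling; scaled
values are clipped at ±10 so single outlier cells cannot dominate a
component. Mitochondrial genes are recognized by a case-insensitive
`MT-` prefix on the gene symbol. Variable genes are selected by the
mean/dispersion-bin method on the log1p scale (mean = log1p(mean expm1),
dispersion = log(var/mean), z-scored within 20 equal-width mean bins,
window 0.1–8, z ≥ 1): the log scales keep the window meaningful across
panel sizes and sequencing depths. By default the total UMI count and the
mitochondrial fraction are regressed out of each gene before scaling
(ordinary least squares with intercept; pivoted QR drops redundant
covariates with a warning).

## Numerical and degenerate-case choices

- **k_max rounding**: the mean of two integer group counts is rounded half
  *up* (k is a count; banker's rounding would be seed-dependent in
  distribution).
- **Elbow rule fallback**: if even the last pair of components drops by
  ≥ 10%, nPC_min = P − 1 with a warning (the curve never flattens; the
  search window is then as wide as the data allow).
- **Reference partitions**: the uniform reference draws are partitioned by
  seeded k-means with 10 restarts — standard gap-statistic practice; a
  `gap_reference = "merge"` switch pushes references through the same
  cluster-and-merge pipeline instead, for fidelity experiments, at a
  substantial cost.
- **Gap standard error**: `gap_statistic()` attaches
  sd(log W*) · √(1 + 1/B), which accounts for the single observed draw as
  well as the Monte-Carlo mean — the band within which a gap on
  structureless data should fall.
- **W normalization**: the 1/(2 n_r) factor of the classical formulation
  is used (switchable to the raw pairwise sum via `dispersion_norm`).
- **Ties**: column maxima tie to the smaller nPC, the sort ties to the
  smaller k, merge distance ties to the lowest group-id pair, and the
  best-candidate tie to the smaller k (prefer coarser major groups). All
  fixed for determinism.
- **Degeneracies**: an all-zero scaled matrix (identical cells) yields a
  zero embedding with a warning; duplicate points make W = 0 and raise an
  error in the gap; an empty filter result raises an error that counts
  both failure modes; if every entry of M is filtered out, the global
  maximum is returned as the single candidate with a warning.
- **Seeding**: every stochastic step (clustering, reference draws) derives
  a sub-seed from the master seed, so whole runs and any subtree of an
  ontology are exactly reproducible.

## What the simulator emulates — and what it does not

`simulate_cells()` draws negative-binomial counts (size = 2 by default)
with per-gene log-normal baseline means, multiplicative marker effects on
disjoint gene sets, log-normal library-size factors (mean 1), and a small
`MT-` block scaled to a 2% expected mitochondrial fraction. The presets
fix the study conditions used across the test suite: `flat5` (5 × 150
cells, 40 markers each at 2.5 natural-log units), `hier3x3` (360 + 160 +
160 cells; the largest major split into three 120-cell subtypes whose 40
markers act at half the major effect), `single_blob` (no structure), and
`pbmc_like` (7 groups, 360 down to 48 cells). Sizes are desk-scale by
design; the marker strengths are chosen so that planted structure is
statistically recoverable at those sizes, which is what makes recovery
failures informative.

Real data differ in ways the simulator does not attempt: no ambient RNA,
doublets, batch effects, cell-cycle structure, or gene-gene correlation
beyond the planted blocks, and marker genes are cleanly disjoint.
Passing tests therefore demonstrate that the algorithm recovers discrete,
marker-driven structure under UMI-like noise — not that it handles
continuous trajectories or tumor-like heterogeneity, which are known
limitations of the approach.

## Problem sizes used in the checks

The simulation-heavy tests run the full pipeline with `gap_B = 25`,
`npc_span = 8` and 30 computed components — parameter-recovery accuracy
saturates well below the production defaults at these data sizes, and the
smaller reference ensemble leaves the gap-increase ranking unchanged on
the presets. The gap-calibration check uses the full `B = 100` on 200
uniform points over 20 seeds; the oracle equivalences use 100 random
instances of up to 100 cells (dispersion) and up to 200 values (AUROC).

## Known limitations

- The clustering backend is SNN + Leiden (modularity). Exact partition
  parity with other community-detection implementations is not a goal;
  the selection machinery only assumes the backend respects separation
  and over-segments under high resolution.
- The gap sweep costs O(span × k_max × B) k-means runs plus dispersion
  evaluations; for tens of thousands of cells, subsample or lower `gap_B`.
- Groups smaller than 3 cells are skipped in DE; candidates whose DE
  table is empty cannot be scored and raise an error.
- Recursion does not re-filter cells and recomputes variable genes within
  each subset; subtype markers that are globally invariant are therefore
  found, but depth is bounded by `min_cells_recurse`.
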