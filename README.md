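# ikap

Identifying major cell population groups in single-cell RNA-seq by
systematically sweeping the two parameters every graph-based clustering
pipeline forces on the analyst: the number of top principal components
(nPC) used to define cell-to-cell similarity, and the resolution that
controls the number of groups k.

## The problem and the method

Clustering and marker-gene (DE) analysis are usually treated as separate
steps, but the choice of (nPC, k) determines which DE genes exist to be
found: too few groups mix cell types, too many produce subgroups with
uninformative markers. `ikap` searches the (nPC, k) plane for sets of
*major*, well-separated groups:

1. **Bounds.** nPC_min is the elbow of the explained-standard-deviation
   curve (first component after which every relative drop is < 10%);
   nPC_max = nPC_min + 20; k_max is the rounded mean of the group counts
   found at resolution r_ini = 1.5 with nPC_min and nPC_max components.
2. **Nested partitions.** For each nPC, cells are clustered at high
   resolution on a shared-nearest-neighbor graph (modularity-maximizing
   Leiden communities; resolution raised from 1.0 in steps of 0.2 until at
   least k_max groups appear), then the two nearest groups — by centroid
   distance in the top-nPC space — are merged iteratively, giving nested
   partitions for k = 1..k_max.
3. **Gap statistic.** Each partition is scored by
   Gap(nPC, k) = E*[log W] − log W, where W = Σ_r D_r / (2 n_r) is the
   pooled within-group pairwise-distance dispersion and the expectation is
   over B uniform draws in the bounding box of the data (partitioned by
   seeded k-means). Large increases M(nPC, k) = Gap(nPC, k) − Gap(nPC, k−1)
   flag k values at which splitting creates well-separated groups.
4. **Candidates.** Entries of M at or below mean + sd are discarded; the
   best surviving entry per column k is kept, sorted by gap increase, and
   accepted greedily when both nPC and k strictly exceed all accepted ones.
   Candidates are named `PC<nPC>K<k>`.
5. **Evaluation.** Per candidate, one-vs-rest Wilcoxon rank-sum DE genes
   (upregulated only) are computed; per group, a CART decision tree on all
   DE genes gives a training relative error; the final classification error
   averages Σ_groups (relative error × group fraction) over nsplit = 5–15.
   The candidate with the lowest error is the best set.
6. **Ontology.** Re-running the sweep inside a group (by default the
   largest, recursively) yields a multi-layer cell-identity tree.

The package also ships a negative-binomial hierarchical simulator with
planted marker genes (`simulate_cells()`, `preset()`) so the whole pipeline
is testable without external downloads.

## Worked example

```r
library(ikap)

sim <- simulate_cells(preset("flat5", seed = 3))      # 5 planted populations
cfg <- ikap_config(gap_B = 25, npc_span = 8, n_pcs = 30, seed = 11)
res <- ikap(sim$counts, cfg)
print(res)
summary(res)
```

```
IKAP sweep of 750 cells: nPC 5..13, k up to 5
1 candidate set(s); best: PC5K5 (classification error 0.0413)
Candidate major-group sets:
  name nPC k gap_increase median_top10_avg_logFC median_top10_avg_log2FC
 PC5K5   5 5       0.3771                  2.438                   3.517
 classification_error n_de_auroc_gt_0.8 n_de_auroc_gt_0.85 n_de_auroc_gt_0.9
              0.04133                27                 21                13
 is_best
    TRUE
```

The sweep recovers the five planted populations as a single candidate
`PC5K5` (5 groups on the top 5 components). Its groups match the simulated
truth exactly (adjusted Rand index 1), the median recovered log fold change
of the top markers (2.44) matches the planted effect (2.5), and 27 DE genes
per group (median) have AUROC > 0.8. `cell_groups(res)` returns the
assignment; `write_results(res, "out/")` writes assignment/DE/gap TSVs and
a JSON manifest; `plot(res)` draws the gap-increase matrix.

For hierarchies:

```r
ont <- build_ontology(sim$counts, cfg, max_depth = 1)   # recurse into the largest group
print(ont)
ontology_leaves(ont)
```

A command-line front end (`inst/cli/ikap.R`) exposes `run`, `ontology`,
`simulate`, `benchmark` (a fixed 20-trial (nPC, r) grid evaluated with the
same metrics) and `summarize` subcommands.

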