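# scborda

Batch integration and Borda consensus feature selection for multi-batch
single-cell RNA-seq comparisons.

## The problem

Comparing two biological groups of cells — diseased versus healthy, or
one brain region versus another — across several scRNA-seq datasets
requires two things to go right. First, the datasets carry systematic
technical differences (batch effects) that must be removed without
erasing the biology. Second, among thousands of measured genes only a
few hundred carry the group signal, and any single ranking method has
blind spots. `scborda` implements a pipeline addressing both, aimed at
computational biologists who want a small, fully testable,
dependency-light implementation with planted-truth benchmarks:

1. **Integration.** Highly variable genes (2000 by default) are selected
   after library-size/log normalization; batches are embedded pairwise
   by a diagonal-regularized CCA (SVD of the cross-product
   $X_s^\top Y_s$ of gene-standardized matrices); mutual nearest
   neighbors in the shared embedding become *anchors*; anchors are
   scored by local-neighborhood overlap and filtered; and each query
   cell is shifted by a distance-weighted average of anchor correction
   vectors (reference minus query expression). Multiple batches merge
   sequentially, largest first.
2. **Ensemble ranking.** Genes are ordered by a per-gene two-sided
   Wilcoxon rank-sum test (ascending p) and, independently, by the gain
   importance of an xgboost classifier trained on the same labels.
3. **Borda consensus.** Each ranker awards gene ranks $0..m-1$ (best
   gene gets $m-1$); grades are totaled, sorted descending, ties broken
   by a seeded shuffle, and the top 100 consensus genes selected:
   $\mathrm{grade}(g) = \sum_r (m - 1 - \mathrm{rank}_r(g))$.
4. **Evaluation.** Selected genes get log2 fold changes, five-level
   regulation categories (strong/moderate down, unchanged,
   moderate/strong up), and — in synthetic mode — exact
   precision/recall against the planted marker set.

A negative-binomial simulator with planted markers, batch distortions
and full ground truth makes every stage testable offline; 10x-style MTX
triplet and CSV readers handle real exports.

## Worked example

```r
library(scborda)

cfg <- case_study_config(
  mode = "synthetic",
  simulation = simulation_config(n_genes = 2000,
                                 n_cells_per_batch = c(1000, 1000),
                                 n_marker_genes = 100,
                                 condition_effect = 1.5,
                                 batch_effect_sd = 0.5, seed = 2024),
  qc = list(min_genes_per_cell = 10, min_cells_per_gene = 3),
  out_dir = "run_reference")
res <- run_case_study(cfg)
res$report
#> recovery_report: precision 0.810, recall 0.810, F1 0.810 (k = 100, markers = 100)
#>   per-ranker recall: wilcoxon 0.940, xgboost_gain 0.600
```

Reading: of the 100 planted marker genes, the Borda top-100 recovers 81
(precision = recall since k equals the marker count). The Wilcoxon
ranker alone recovers 94; the boosted-tree gain ranker alone 60 — greedy
boosting only ever splits on a subset of mutually redundant markers, so
its recovery saturates, and the consensus lands between the two. The run
directory holds both rankings, `consensus.csv` (grades and per-ranker
ranks), `top_genes.txt`, the anchor table, the regulation-category table
and heatmap, `recovery.json`, and a `manifest.json` with every
parameter, seed, merge order and artifact checksum; rerunning the same
config reproduces the CSVs byte for byte.

## Analysis workflow

Numbered drivers under `analysis/` (run from the repository root)
narrate the full study over synthetic cohorts and write their tables
under `results/`:

```sh
Rscript analysis/01_simulate_cohorts.R        # three cohorts as MTX triplets
Rscript analysis/02_integration_diagnostics.R # batch silhouette before/after
Rscript analysis/03_case_studies.R            # three end-to-end case studies
Rscript analysis/04_recovery_summary.R        # collated summary table
```

The three case studies mirror a hippocampus-like many-batch
disease-vs-control cohort, a cortex-like cohort, and a disease-only
cohort contrasted by region.

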