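#!/usr/bin/env Rscript
# Build the three synthetic cohorts that stand in for the three case
# studies: a many-batch hippocampus-like AD-vs-control cohort, a
# cortex-like AD-vs-control cohort, and an AD-only cohort contrasted by
# brain region. Each cohort is written as a 10x-style MTX triplet with
# cell metadata and its generating config, so every later stage can be
# driven from files alone.

suppressPackageStartupMessages(library(scborda))

out_root <- "results/data"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

cohorts <- list(
  hippocampus = simulation_config(
    n_genes = 1000, n_cells_per_batch = rep(80, 14), n_batches = 14,
    n_marker_genes = 60, condition_effect = rep(c(1.5, -1.5), 30),
    batch_effect_sd = 0.5, seed = 101),
  cortex = simulation_config(
    n_genes = 1000, n_cells_per_batch = rep(120, 8), n_batches = 8,
    n_marker_genes = 60, condition_effect = rep(c(1.5, -1.5), 30),
    batch_effect_sd = 0.5, seed = 102),
  region_ad = simulation_config(
    n_genes = 1000, n_cells_per_batch = rep(100, 4), n_batches = 4,
    n_marker_genes = 60, condition_effect = rep(c(1.5, -1.5), 30),
    batch_effect_sd = 0.5,
    condition_column = "region",
    condition_levels = c("hippocampus", "cortex"), seed = 103)
)

for (name in names(cohorts)) {
  cfg <- cohorts[[name]]
  sim <- simulate_dataset(cfg)
  dir <- file.path(out_root, name)
  write_mtx_dataset(sim$counts, dir, config = cfg)
  writeLines(sim$truth$marker_gene_ids, file.path(dir, "true_markers.txt"))
  cat(sprintf("%-12s %d genes x %d cells in %d batches -> %s (%d planted markers)\n",
              name, length(sim$counts$gene_ids), length(sim$counts$cell_ids),
              cfg$n_batches, dir, length(sim$truth$marker_gene_ids)))
}
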