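#!/usr/bin/env Rscript
# Collate the three case-study runs into one summary table: recovery of
# the planted markers by the consensus and by each single ranker, plus
# the distribution of the five regulation categories among the selected
# genes. Requires 03_case_studies.R to have run.

suppressPackageStartupMessages(library(scborda))

run_root <- "results/case_studies"
studies <- list.dirs(run_root, recursive = FALSE)
if (length(studies) == 0)
  stop("no case-study runs found; run analysis/03_case_studies.R first")

rows <- lapply(studies, function(dir) {
  rec <- jsonlite::read_json(file.path(dir, "recovery.json"))
  cats <- read.csv(file.path(dir, "top_genes_categories.csv"))
  tab <- table(factor(cats$category,
                      levels = c("strong_down", "moderate_down", "unchanged",
                                 "moderate_up", "strong_up")))
  data.frame(case_study = basename(dir),
             recall = rec$recall, precision = rec$precision, f1 = rec$f1,
             wilcoxon_recall = rec$per_ranker_recall$wilcoxon,
             gain_recall = rec$per_ranker_recall$xgboost_gain,
             strong_down = tab[["strong_down"]],
             moderate_down = tab[["moderate_down"]],
             unchanged = tab[["unchanged"]],
             moderate_up = tab[["moderate_up"]],
             strong_up = tab[["strong_up"]])
})
summary <- do.call(rbind, rows)
write.csv(summary, "results/case_study_summary.csv", row.names = FALSE)
print(summary, row.names = FALSE)
cat("\nwrote results/case_study_summary.csv\n")
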