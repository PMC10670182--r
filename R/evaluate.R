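#' Per-gene log2 fold change between two cell groups
#'
#' Computed on de-logged expression: `log2((mean_2 + eps)/(mean_1 + eps))`
#' where group 2 is the second factor level (disease by convention) and
#' `eps` is a small pseudomean guarding against empty means.
#'
#' @param m an `integrated_matrix` or `normalized_matrix` (log-scale
#'   values).
#' @param labels per-cell condition with exactly two levels.
#' @param eps pseudomean (default 1e-9).
#' @return named numeric vector of log2 fold changes per gene.
#' @export
compute_log2fc <- function(m, labels, eps = 1e-9) {
  x <- as.matrix(m$values)
  labels <- droplevels(as.factor(labels))
  stopifnot(length(labels) == ncol(x))
  if (nlevels(labels) != 2L)
    stop("compute_log2fc: labels must have exactly two levels", call. = FALSE)
  g1 <- labels == levels(labels)[1L]
  g2 <- labels == levels(labels)[2L]
  if (!any(g1) || !any(g2))
    stop("compute_log2fc: both groups must be nonempty", call. = FALSE)
  expd <- expm1(x)
  setNames(log2((pmax(rowMeans(expd[, g2, drop = FALSE]), 0) + eps) /
                  (pmax(rowMeans(expd[, g1, drop = FALSE]), 0) + eps)),
           rownames(x))
}

#' Five-level regulation categories from log2 fold changes
#'
#' Deterministic rule mirroring the usual five-color regulation heatmap:
#' `|log2fc| <= t_moderate` is `unchanged`; `t_moderate < |log2fc| <=
#' t_strong` is `moderate_up`/`moderate_down` by sign; `|log2fc| >
#' t_strong` is `strong_up`/`strong_down`.
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @param thresholds `c(t_moderate, t_strong)` with
#'   `0 < t_moderate < t_strong`; default `c(0.5, 1.5)` log2 units.
#' @return ordered factor with levels `strong_down`, `moderate_down`,
#'   `unchanged`, `moderate_up`, `strong_up`.
#' @export
categorize <- function(log2fc, thresholds = c(0.5, 1.5)) {
  stopifnot(length(thresholds) == 2, thresholds[1] > 0,
            thresholds[1] < thresholds[2])
  t_mod <- thresholds[1]
  t_str <- thresholds[2]
  lvls <- c("strong_down", "moderate_down", "unchanged",
            "moderate_up", "strong_up")
  out <- rep("unchanged", length(log2fc))
  out[log2fc > t_mod & log2fc <= t_str] <- "moderate_up"
  out[log2fc > t_str] <- "strong_up"
  out[log2fc < -t_mod & log2fc >= -t_str] <- "moderate_down"
  out[log2fc < -t_str] <- "strong_down"
  factor(out, levels = lvls, ordered = TRUE)
}

#' Score a selected gene set against planted ground truth
#'
#' Exact set-intersection metrics of the selection versus the planted
#' marker genes, plus the consensus rank of every marker and, when the
#' contributing rankings are supplied, each single ranker's marginal
#' recall at the same cutoff.
#'
#' @param selected character vector of selected genes (e.g. the top-100
#'   consensus set).
#' @param truth a `ground_truth` from [simulate_dataset()].
#' @param consensus a [borda_aggregate()] result (for marker ranks).
#' @param rankings optional list of [ranked_genes()] objects for
#'   per-ranker marginal recovery at `length(selected)`.
#' @return object of class `recovery_report` with `precision`, `recall`,
#'   `f1`, `n_selected`, `n_markers`, `marker_ranks`, `per_ranker_recall`.
#' @export
recovery_report <- function(selected, truth, consensus = NULL,
                            rankings = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  markers <- truth$marker_gene_ids
  hits <- intersect(selected, markers)
  precision <- if (length(selected)) length(hits) / length(selected) else 0
  recall <- if (length(markers)) length(hits) / length(markers) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  marker_ranks <- NULL
  if (!is.null(consensus)) {
    stopifnot(inherits(consensus, "consensus_result"))
    marker_ranks <- setNames(match(markers, consensus$ordering), markers)
  }
  per_ranker <- NULL
  if (!is.null(rankings) && length(markers)) {
    per_ranker <- vapply(rankings, function(r) {
      top <- head(r$ordered_genes, length(selected))
      length(intersect(top, markers)) / length(markers)
    }, numeric(1))
    names(per_ranker) <- vapply(rankings, `[[`, "", "ranker_name")
  }
  structure(list(precision = precision, recall = recall, f1 = f1,
                 n_selected = length(selected), n_markers = length(markers),
                 marker_ranks = marker_ranks,
                 per_ranker_recall = per_ranker),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery_report: precision %.3f, recall %.3f, F1 %.3f (k = %d, markers = %d)\n",
              x$precision, x$recall, x$f1, x$n_selected, x$n_markers))
  if (!is.null(x$per_ranker_recall))
    cat("  per-ranker recall:",
        paste(sprintf("%s %.3f", names(x$per_ranker_recall),
                      x$per_ranker_recall), collapse = ", "), "\n")
  invisible(x)
}

#' Write the regulation-category table and a best-effort heatmap
#'
#' Always writes a deterministic CSV (gene, log2fc, category and the
#' consensus rank when available). When `pheatmap` and a graphics device
#' are available a five-color category heatmap PNG is rendered; image
#' rendering failures are tolerated.
#'
#' @param log2fc named numeric vector of log2 fold changes for the
#'   selected genes.
#' @param categories factor from [categorize()] aligned to `log2fc`.
#' @param path_prefix output path prefix; writes
#'   `<prefix>_categories.csv` and best-effort `<prefix>_heatmap.png`.
#' @param consensus_rank optional named integer vector of consensus ranks.
#' @return path of the CSV, invisibly.
#' @export
render_heatmap <- function(log2fc, categories, path_prefix,
                           consensus_rank = NULL) {
  stopifnot(length(log2fc) == length(categories))
  df <- data.frame(gene_id = names(log2fc),
                   log2fc = unname(log2fc),
                   category = as.character(categories),
                   stringsAsFactors = FALSE)
  if (!is.null(consensus_rank))
    df$consensus_rank <- unname(consensus_rank[df$gene_id])
  csv_path <- paste0(path_prefix, "_categories.csv")
  write.csv(df, csv_path, row.names = FALSE)
  png_path <- paste0(path_prefix, "_heatmap.png")
  tryCatch({
    if (requireNamespace("pheatmap", quietly = TRUE)) {
      code <- matrix(as.integer(categories) - 3L, ncol = 1,
                     dimnames = list(names(log2fc), "regulation"))
      pal <- c("#a50026", "#f46d43", "#ffffbf", "#a6d96a", "#1a9850")
      grDevices::png(png_path, width = 480,
                     height = max(480, 12 * nrow(code)))
      pheatmap::pheatmap(code, cluster_rows = FALSE, cluster_cols = FALSE,
                         color = pal, breaks = seq(-2.5, 2.5, by = 1),
                         legend_breaks = -2:2,
                         legend_labels = levels(categories),
                         fontsize_row = 6)
      grDevices::dev.off()
    }
  }, error = function(e) invisible(NULL))
  invisible(csv_path)
}
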