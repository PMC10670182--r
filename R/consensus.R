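#' Fuse ranked gene lists by Borda rank aggregation
#'
#' Each ranker awards every gene a rank value between 0 and m - 1: its
#' top gene gets m - 1 points, its bottom gene 0. Points are totaled
#' across rankers into a cumulative grade and genes are arranged in
#' descending grade order; ties are resolved by a random permutation
#' drawn from a generator seeded with `tie_seed`, so runs are
#' replayable. Every ranker hands out each value of 0..m-1 exactly once,
#' so the grade total is always r*m*(m-1)/2 for r rankers.
#'
#' @param rankings list of >= 2 [ranked_genes()] objects over the
#'   identical gene set.
#' @param tie_seed integer seed for the tie-break permutation.
#' @return object of class `consensus_result`: `grades` (named integer
#'   vector), `ordering` (genes by descending grade), `per_ranker_ranks`
#'   (1-based rank of each gene under each ranker), `tie_seed`, `m`.
#' @export
borda_aggregate <- function(rankings, tie_seed = 0L) {
  stopifnot(is.list(rankings), length(rankings) >= 2)
  rankings <- lapply(rankings, function(r) {
    if (!inherits(r, "ranked_genes"))
      stop("borda_aggregate: rankings must be ranked_genes objects", call. = FALSE)
    r
  })
  genes <- sort(rankings[[1L]]$ordered_genes)
  for (r in rankings[-1L]) {
    other <- sort(r$ordered_genes)
    if (!identical(genes, other)) {
      diff <- union(setdiff(genes, other), setdiff(other, genes))
      stop(sprintf("borda_aggregate: rankings cover different gene sets; symmetric difference: %s",
                   paste(diff, collapse = ", ")), call. = FALSE)
    }
  }
  m <- length(genes)
  grades <- setNames(rep(0L, m), genes)
  per_ranker <- matrix(NA_integer_, m, length(rankings),
                       dimnames = list(genes, vapply(rankings, `[[`,
                                                     "", "ranker_name")))
  for (j in seq_along(rankings)) {
    og <- rankings[[j]]$ordered_genes
    grades[og] <- grades[og] + (m - seq_len(m))
    per_ranker[og, j] <- seq_len(m)
  }
  set.seed(tie_seed)
  tie_break <- sample.int(m)
  ord <- order(-grades, tie_break)
  structure(list(grades = grades,
                 ordering = genes[ord],
                 per_ranker_ranks = per_ranker,
                 tie_seed = as.integer(tie_seed),
                 m = m),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d genes, grade sum %d, tie_seed %d\n",
              x$m, sum(x$grades), x$tie_seed))
  cat("  top:", paste(head(x$ordering, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Select the top-k genes of a consensus ordering
#'
#' @param consensus a [borda_aggregate()] result.
#' @param k number of genes to keep (default 100).
#' @return character vector of the first k genes of the consensus
#'   ordering.
#' @export
select_top_k <- function(consensus, k = 100) {
  stopifnot(inherits(consensus, "consensus_result"))
  if (k < 1 || k > consensus$m)
    stop(sprintf("select_top_k: k = %d outside [1, %d]", k, consensus$m),
         call. = FALSE)
  consensus$ordering[seq_len(k)]
}

#' Write a consensus table as CSV
#'
#' Columns: consensus_rank, gene_id, cumulative_grade and the 1-based
#' rank under each contributing ranker.
#'
#' @param consensus a [borda_aggregate()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_consensus_csv <- function(consensus, path) {
  stopifnot(inherits(consensus, "consensus_result"))
  og <- consensus$ordering
  df <- data.frame(consensus_rank = seq_along(og),
                   gene_id = og,
                   cumulative_grade = unname(consensus$grades[og]))
  pr <- consensus$per_ranker_ranks[og, , drop = FALSE]
  colnames(pr) <- paste0(colnames(pr), "_rank")
  df <- cbind(df, as.data.frame(pr, row.names = NULL))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
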