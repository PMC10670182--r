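#' Ranked gene list container
#'
#' A total order over the m input genes produced by one ranker, with the
#' per-gene score that drove the ordering.
#'
#' @param table data.frame in rank order with at least `gene_id` and
#'   `score` columns.
#' @param ranker_name string identifying the ranker.
#' @return object of class `ranked_genes` with fields `ordered_genes`,
#'   `scores`, `table`, `ranker_name`, `m`.
#' @export
ranked_genes <- function(table, ranker_name) {
  stopifnot(is.data.frame(table), !is.null(table$gene_id), !is.null(table$score))
  if (anyDuplicated(table$gene_id))
    stop("ranked_genes: gene ids must be unique", call. = FALSE)
  table$rank <- seq_len(nrow(table))
  rownames(table) <- NULL
  structure(list(ordered_genes = table$gene_id,
                 scores = setNames(table$score, table$gene_id),
                 table = table,
                 ranker_name = ranker_name,
                 m = nrow(table)),
            class = "ranked_genes")
}

#' @export
print.ranked_genes <- function(x, ...) {
  cat(sprintf("ranked_genes (%s): %d genes; head: %s\n", x$ranker_name, x$m,
              paste(head(x$ordered_genes, 5), collapse = ", ")))
  invisible(x)
}

#' Write a ranked gene list as CSV (rank, gene_id, score, ranker_name)
#' @param r a `ranked_genes` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ranking_csv <- function(r, path) {
  stopifnot(inherits(r, "ranked_genes"))
  df <- data.frame(rank = seq_len(r$m), gene_id = r$ordered_genes,
                   score = unname(r$scores[r$ordered_genes]),
                   ranker_name = r$ranker_name)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Two-sided Wilcoxon rank-sum p-value for one gene. Mid-ranks for ties;
# exact distribution (pwilcox) when both groups have <= `exact_limit`
# observations and the pooled sample is tie-free, otherwise the
# tie-corrected normal approximation with continuity correction.
wilcoxon_p <- function(x, g1, g2, exact_limit = 25) {
  n1 <- length(g1)
  n2 <- length(g2)
  r <- rank(x)
  U <- sum(r[g1]) - n1 * (n1 + 1) / 2
  nties <- table(x)
  has_ties <- any(nties > 1)
  if (n1 <= exact_limit && n2 <= exact_limit && !has_ties) {
    p <- if (U > n1 * n2 / 2)
      2 * pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    else
      2 * pwilcox(U, n1, n2)
    return(list(p = min(1, p), U = U))
  }
  mu <- n1 * n2 / 2
  z <- U - mu
  n <- n1 + n2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(p = 1, U = U))
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))
  list(p = min(1, p), U = U)
}

#' Rank genes by the two-sided Wilcoxon rank-sum test
#'
#' Runs a per-gene two-sided rank-sum test between the two condition
#' groups: mid-rank tie handling, exact null distribution for small
#' tie-free groups (both sizes <= 25), tie-corrected normal approximation
#' with continuity correction otherwise. Constant genes get p = 1 by
#' convention. Genes are ordered by ascending p-value, ties broken by
#' descending absolute log2 fold change of the de-logged group means,
#' residual ties by gene identifier; `order_by = "statistic"` instead
#' orders by the absolute centered rank-sum statistic.
#'
#' @param m an `integrated_matrix` or `normalized_matrix`.
#' @param labels per-cell condition with exactly two levels, aligned to
#'   the matrix columns.
#' @param order_by `"p_value"` (default) or `"statistic"`.
#' @param eps pseudomean in the fold-change tie-break.
#' @return a [ranked_genes()] object; `table` carries `p_value`,
#'   `statistic` (centered rank-sum) and `log2fc`.
#' @export
wilcoxon_rank <- function(m, labels, order_by = c("p_value", "statistic"),
                          eps = 1e-9) {
  order_by <- match.arg(order_by)
  x <- as.matrix(m$values)
  labels <- as.factor(labels)
  stopifnot(length(labels) == ncol(x))
  labels <- droplevels(labels)
  if (nlevels(labels) != 2L)
    stop("wilcoxon_rank: labels must have exactly two levels", call. = FALSE)
  g1 <- which(labels == levels(labels)[1L])
  g2 <- which(labels == levels(labels)[2L])
  if (length(g1) < 2L || length(g2) < 2L)
    stop("wilcoxon_rank: each group needs at least two cells", call. = FALSE)
  n1 <- length(g1)
  n2 <- length(g2)
  res <- vapply(seq_len(nrow(x)), function(i) {
    xi <- x[i, ]
    if (max(xi) == min(xi)) return(c(1, 0))
    w <- wilcoxon_p(xi, g1, g2)
    c(w$p, w$U - n1 * n2 / 2)
  }, numeric(2))
  p <- res[1L, ]
  stat <- res[2L, ]
  expd <- expm1(x)
  # means clamped at zero so inputs that are not true log-expression
  # (e.g. centered values) cannot produce NaN in the tie-break
  lfc <- log2((pmax(rowMeans(expd[, g2, drop = FALSE]), 0) + eps) /
                (pmax(rowMeans(expd[, g1, drop = FALSE]), 0) + eps))
  ord <- if (order_by == "p_value")
    order(p, -abs(lfc), rownames(x))
  else
    order(-abs(stat), rownames(x))
  tab <- data.frame(gene_id = rownames(x)[ord],
                    score = p[ord],
                    p_value = p[ord],
                    statistic = stat[ord],
                    log2fc = lfc[ord],
                    stringsAsFactors = FALSE)
  ranked_genes(tab, "wilcoxon")
}

#' Rank genes by gradient-boosted-tree gain importance
#'
#' Fits an xgboost binary classifier (cells x genes) on the condition
#' labels with default hyperparameters, single-threaded for
#' reproducibility, and ranks genes by descending total gain (the summed
#' split-gain contribution across all trees). Genes the model never
#' splits on carry zero gain and are placed after all used genes,
#' ordered by gene identifier.
#'
#' @param m an `integrated_matrix` or `normalized_matrix`.
#' @param labels per-cell condition with exactly two levels.
#' @param nrounds boosting rounds (default 100, the usual library
#'   default for the number of estimators).
#' @param params named list of extra xgboost parameters; merged over the
#'   defaults (`binary:logistic`, `tree_method = "hist"`, `nthread = 1`).
#' @param seed RNG seed set before training.
#' @return a [ranked_genes()] object; scores are gain fractions summing
#'   to 1 over used genes.
#' @export
gain_rank <- function(m, labels, nrounds = 100, params = list(), seed = 0L) {
  labels <- as.factor(labels)
  x <- m$values
  stopifnot(length(labels) == ncol(x))
  labels <- droplevels(labels)
  if (nlevels(labels) != 2L)
    stop("gain_rank: labels must have exactly two levels", call. = FALSE)
  y <- as.integer(labels == levels(labels)[2L])
  xt <- Matrix::t(methods::as(methods::as(x, "generalMatrix"), "CsparseMatrix"))
  colnames(xt) <- m$gene_ids
  dtrain <- xgboost::xgb.DMatrix(xt, label = y, nthread = 1)
  defaults <- list(objective = "binary:logistic", tree_method = "hist",
                   nthread = 1)
  defaults[names(params)] <- params
  set.seed(seed)
  bst <- xgboost::xgb.train(params = defaults, data = dtrain,
                            nrounds = nrounds, verbose = 0)
  imp <- xgboost::xgb.importance(model = bst)
  gain <- setNames(rep(0, length(m$gene_ids)), m$gene_ids)
  if (!is.null(imp) && nrow(imp) > 0)
    gain[imp$Feature] <- imp$Gain
  ord <- order(-gain, names(gain))
  tab <- data.frame(gene_id = names(gain)[ord],
                    score = unname(gain[ord]),
                    stringsAsFactors = FALSE)
  ranked_genes(tab, "xgboost_gain")
}
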