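#' @importFrom stats rlnorm rnbinom rnorm pnorm pwilcox quantile loess predict
#'   var cor prcomp dist median setNames
#' @importFrom utils head write.csv read.csv
#' @importFrom methods as is
NULL

# Row variances of a dense matrix (two-pass, unbiased).
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(0, nrow(x)))
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1L)
}

# L2-normalize the rows of a matrix; all-zero rows are left untouched.
l2_normalize_rows <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  x / nrm
}

# Squared Euclidean cross-distances between rows of a and rows of b.
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Mean silhouette width of cells grouped by a label, computed in the space
# of the top principal components of the (genes x cells) expression matrix.
# Used to quantify how batch-separable an embedding is.
#' Mean silhouette width by grouping label in PCA space
#'
#' Convenience diagnostic: projects cells onto the leading principal
#' components of the expression matrix and returns the mean silhouette
#' width of the grouping. Larger values mean the groups (e.g. batches)
#' are more separable; successful batch correction should reduce the
#' batch silhouette.
#'
#' @param values genes x cells numeric matrix (log scale).
#' @param group per-cell grouping label (e.g. batch).
#' @param n_pcs number of principal components for the embedding.
#' @param max_cells subsample cap for the silhouette computation (the
#'   full pairwise distance matrix is quadratic in cells).
#' @param seed seed for the subsample.
#' @return mean silhouette width (numeric scalar).
#' @export
batch_silhouette <- function(values, group, n_pcs = 10, max_cells = 500,
                             seed = 1L) {
  values <- as.matrix(values)
  group <- as.factor(group)
  stopifnot(ncol(values) == length(group))
  if (ncol(values) > max_cells) {
    set.seed(seed)
    idx <- sort(sample.int(ncol(values), max_cells))
    values <- values[, idx, drop = FALSE]
    group <- droplevels(group[idx])
  }
  n_pcs <- min(n_pcs, ncol(values) - 1L, nrow(values))
  pc <- prcomp(t(values), center = TRUE, scale. = FALSE, rank. = n_pcs)
  sil <- cluster::silhouette(as.integer(group), dist(pc$x))
  mean(sil[, "sil_width"])
}
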