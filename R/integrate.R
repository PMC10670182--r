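#' Canonical correlation embedding of two cell sets
#'
#' Embeds the cells of two datasets into a shared d-dimensional space by
#' a diagonal-regularized CCA: genes are standardized within each
#' dataset and the top-d singular structure of the cross-product
#' \eqn{X^\top Y} is computed. The left/right singular vectors are the
#' per-cell coordinates of the two datasets; the canonical correlation
#' of component i is the correlation between the two gene-space
#' canonical variates \eqn{X u_i} and \eqn{Y v_i} (nonnegative since
#' singular values are), and components are ordered so the correlations
#' are nonincreasing. Raw singular values are retained for diagnostics.
#'
#' @param a,b `normalized_matrix` objects restricted to the same genes
#'   (typically a shared HVG set).
#' @param d number of canonical components (default 20).
#' @return object of class `cca_embedding` with per-dataset cell
#'   coordinate blocks, `canonical_correlations` and `singular_values`.
#' @export
cca_embed <- function(a, b, d = 20) {
  stopifnot(inherits(a, "normalized_matrix"), inherits(b, "normalized_matrix"))
  if (!identical(a$gene_ids, b$gene_ids)) {
    if (!setequal(a$gene_ids, b$gene_ids))
      stop("cca_embed: datasets must be restricted to the same genes",
           call. = FALSE)
    b$values <- b$values[a$gene_ids, , drop = FALSE]
    b$gene_ids <- a$gene_ids
  }
  X <- as.matrix(a$values)
  Y <- as.matrix(b$values)
  sd_x <- sqrt(row_vars(X))
  sd_y <- sqrt(row_vars(Y))
  dead <- sd_x == 0 & sd_y == 0
  if (any(dead)) {
    warning(sprintf("cca_embed: dropping %d gene(s) with zero variance in both datasets",
                    sum(dead)))
    X <- X[!dead, , drop = FALSE]
    Y <- Y[!dead, , drop = FALSE]
    sd_x <- sd_x[!dead]
    sd_y <- sd_y[!dead]
  }
  sd_x[sd_x == 0] <- 1
  sd_y[sd_y == 0] <- 1
  Xs <- (X - rowMeans(X)) / sd_x
  Ys <- (Y - rowMeans(Y)) / sd_y
  max_d <- min(ncol(Xs), ncol(Ys), nrow(Xs))
  if (d > max_d)
    stop(sprintf("cca_embed: d = %d exceeds the rank bound %d", d, max_d),
         call. = FALSE)
  K <- crossprod(Xs, Ys)
  s <- svd(K, nu = d, nv = d)
  U <- s$u
  V <- s$v
  sv <- s$d[seq_len(d)]
  PA <- Xs %*% U
  PB <- Ys %*% V
  cc <- colSums(PA * PB) /
    (sqrt(colSums(PA^2)) * sqrt(colSums(PB^2)))
  cc[!is.finite(cc)] <- 0
  ord <- order(cc, decreasing = TRUE)
  U <- U[, ord, drop = FALSE]
  V <- V[, ord, drop = FALSE]
  rownames(U) <- colnames(X)
  rownames(V) <- colnames(Y)
  structure(list(loadings_a = U, loadings_b = V,
                 canonical_correlations = cc[ord],
                 singular_values = sv[ord],
                 d = d,
                 cell_ids_a = colnames(X), cell_ids_b = colnames(Y),
                 genes_used = rownames(X)),
            class = "cca_embedding")
}

#' @export
print.cca_embedding <- function(x, ...) {
  cat(sprintf("cca_embedding: %d + %d cells, d = %d, cc[1] = %.3f\n",
              length(x$cell_ids_a), length(x$cell_ids_b), x$d,
              x$canonical_correlations[1]))
  invisible(x)
}

# k-nearest-neighbor indices of rows of `query` among rows of `ref`
# (dense search; adequate at desk scale).
knn_indices <- function(query, ref, k, exclude_self = FALSE) {
  d2 <- cross_dist2(query, ref)
  t(vapply(seq_len(nrow(query)), function(i) {
    di <- d2[i, ]
    if (exclude_self) di[i] <- Inf
    order(di)[seq_len(k)]
  }, integer(k)))
}

#' Find mutual-nearest-neighbor anchors between two embedded datasets
#'
#' Cell loadings are L2-normalized per cell and a Euclidean
#' k-nearest-neighbor search is run in both directions; a cross-dataset
#' cell pair is retained as an anchor iff it is mutual (each cell lies
#' among the other's `k_anchor` nearest cross-dataset neighbors). Raw
#' anchors carry score 1 prior to filtering.
#'
#' @param e a [cca_embed()] result.
#' @param k_anchor neighborhood size (default 5).
#' @return object of class `anchor_set` with a `pairs` data.frame
#'   (`cell_a`, `cell_b`, `score` plus integer indices).
#' @export
find_anchors <- function(e, k_anchor = 5) {
  stopifnot(inherits(e, "cca_embedding"), k_anchor >= 1)
  A <- l2_normalize_rows(e$loadings_a)
  B <- l2_normalize_rows(e$loadings_b)
  if (k_anchor > nrow(A) || k_anchor > nrow(B))
    stop(sprintf("find_anchors: k_anchor = %d exceeds dataset size (%d, %d)",
                 k_anchor, nrow(A), nrow(B)), call. = FALSE)
  nn_ab <- knn_indices(A, B, k_anchor)
  nn_ba <- knn_indices(B, A, k_anchor)
  hits_ab <- matrix(FALSE, nrow(A), nrow(B))
  hits_ab[cbind(rep(seq_len(nrow(A)), k_anchor), as.vector(nn_ab))] <- TRUE
  hits_ba <- matrix(FALSE, nrow(B), nrow(A))
  hits_ba[cbind(rep(seq_len(nrow(B)), k_anchor), as.vector(nn_ba))] <- TRUE
  mutual <- which(hits_ab & t(hits_ba), arr.ind = TRUE)
  mutual <- mutual[order(mutual[, 1L], mutual[, 2L]), , drop = FALSE]
  pairs <- data.frame(
    cell_a = e$cell_ids_a[mutual[, 1L]],
    cell_b = e$cell_ids_b[mutual[, 2L]],
    idx_a = as.integer(mutual[, 1L]),
    idx_b = as.integer(mutual[, 2L]),
    score = 1,
    stringsAsFactors = FALSE)
  structure(list(pairs = pairs, k_anchor = k_anchor), class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("anchor_set: %d pairs, score range [%.3g, %.3g]\n",
              nrow(x$pairs),
              if (nrow(x$pairs)) min(x$pairs$score) else NA,
              if (nrow(x$pairs)) max(x$pairs$score) else NA))
  invisible(x)
}

#' Score anchors by shared-neighbor overlap and filter
#'
#' Each cell's neighborhood is the union of its `k_score` nearest
#' neighbors within dataset A and within dataset B (so both within- and
#' cross-dataset structure contributes). The raw anchor score is the
#' size of the intersection of the two anchored cells' neighborhoods;
#' raw scores are rescaled to \[0, 1\] by clipping at the 0.01 and 0.90
#' quantiles. Anchors scoring below `min_score` are removed; incorrect
#' anchors that land in unrelated neighborhoods get near-zero scores.
#'
#' @param anchors an `anchor_set` from [find_anchors()].
#' @param e the [cca_embed()] embedding the anchors came from.
#' @param k_score neighborhood size for scoring (default 30).
#' @param min_score retention threshold on the rescaled score
#'   (default 0.1).
#' @return the filtered `anchor_set` with updated scores.
#' @export
filter_anchors <- function(anchors, e, k_score = 30, min_score = 0.1) {
  stopifnot(inherits(anchors, "anchor_set"), inherits(e, "cca_embedding"),
            k_score >= 1)
  if (nrow(anchors$pairs) == 0)
    stop("no anchors retained: anchor set is empty before filtering",
         call. = FALSE)
  A <- l2_normalize_rows(e$loadings_a)
  B <- l2_normalize_rows(e$loadings_b)
  nA <- nrow(A)
  nB <- nrow(B)
  kA <- min(k_score, nA)
  kB <- min(k_score, nB)
  C <- rbind(A, B)
  # neighborhood of every cell: k nearest within A plus k nearest within B,
  # indexed into the combined set (self excluded within the own block)
  nn_in_a <- knn_indices(C, A, kA, exclude_self = FALSE)
  nn_in_b <- knn_indices(C, B, kB, exclude_self = FALSE)
  neigh <- lapply(seq_len(nA + nB), function(i)
    c(nn_in_a[i, ], nA + nn_in_b[i, ]))
  raw <- vapply(seq_len(nrow(anchors$pairs)), function(j) {
    ia <- anchors$pairs$idx_a[j]
    ib <- nA + anchors$pairs$idx_b[j]
    length(intersect(neigh[[ia]], neigh[[ib]]))
  }, numeric(1))
  q <- quantile(raw, c(0.01, 0.90), names = FALSE)
  if (q[2] > q[1]) {
    score <- pmin(1, pmax(0, (raw - q[1]) / (q[2] - q[1])))
  } else {
    score <- rep(1, length(raw))
  }
  keep <- score >= min_score
  if (!any(keep))
    stop("no anchors retained after filtering; relax min_score or increase k_score",
         call. = FALSE)
  out <- anchors
  out$pairs <- anchors$pairs[keep, , drop = FALSE]
  out$pairs$score <- score[keep]
  rownames(out$pairs) <- NULL
  out$k_score <- k_score
  out$min_score <- min_score
  out
}

#' Apply anchor-based batch correction to a query dataset
#'
#' Every anchor contributes a correction vector: reference-cell minus
#' query-cell expression over the shared genes (the pairwise expression
#' difference estimates the batch effect). Each query cell is shifted by
#' a weighted average of the vectors of its `k_weight` nearest anchors
#' (Gaussian kernel over L2-normalized embedding distance, bandwidth set
#' to half the distance to the k-th selected anchor). Reference cells
#' are returned unchanged.
#'
#' @param query,reference `normalized_matrix` objects over the same genes.
#' @param anchors filtered `anchor_set`; `cell_a` must index reference
#'   cells and `cell_b` query cells (the [cca_embed()] convention with
#'   `a = reference`).
#' @param e the [cca_embed()] embedding used for the anchor search.
#' @param k_weight number of anchors averaged per query cell
#'   (default 100; clipped to the anchor count with a warning).
#' @return object of class `integrated_matrix`: corrected genes x cells
#'   values (reference cells first), combined metadata and provenance.
#' @export
apply_correction <- function(query, reference, anchors, e, k_weight = 100) {
  stopifnot(inherits(query, "normalized_matrix"),
            inherits(reference, "normalized_matrix"),
            inherits(anchors, "anchor_set"), inherits(e, "cca_embedding"))
  n_anchor <- nrow(anchors$pairs)
  if (n_anchor == 0)
    stop("apply_correction: anchor set is empty", call. = FALSE)
  if (k_weight > n_anchor) {
    warning(sprintf("k_weight = %d exceeds the %d available anchors; clipping",
                    k_weight, n_anchor))
    k_weight <- n_anchor
  }
  ref_x <- as.matrix(reference$values)
  qry_x <- as.matrix(query$values)
  stopifnot(identical(rownames(ref_x), rownames(qry_x)))
  vecs <- ref_x[, anchors$pairs$cell_a, drop = FALSE] -
    qry_x[, anchors$pairs$cell_b, drop = FALSE]
  Q <- l2_normalize_rows(e$loadings_b)
  anchor_coords <- Q[anchors$pairs$idx_b, , drop = FALSE]
  d2 <- cross_dist2(Q, anchor_coords)
  corrected <- qry_x
  for (i in seq_len(ncol(qry_x))) {
    di <- sqrt(d2[i, ])
    sel <- order(di)[seq_len(k_weight)]
    dk <- di[sel[k_weight]]
    if (dk == 0) {
      w <- rep(1, k_weight)
    } else {
      bw <- dk / 2
      w <- exp(-di[sel]^2 / (2 * bw^2))
    }
    w <- w / sum(w)
    corrected[, i] <- qry_x[, i] + as.vector(vecs[, sel, drop = FALSE] %*% w)
  }
  values <- cbind(ref_x, corrected)
  meta <- rbind(reference$cell_meta, query$cell_meta)
  rownames(meta) <- NULL
  structure(list(values = values,
                 gene_ids = rownames(values),
                 cell_ids = colnames(values),
                 cell_meta = meta,
                 hvg_ids = reference$hvg_ids,
                 correction_provenance = list(k_weight = k_weight,
                                              n_anchors = n_anchor),
                 anchors = anchors$pairs),
            class = "integrated_matrix")
}

#' @export
print.integrated_matrix <- function(x, ...) {
  cat(sprintf("integrated_matrix: %d genes x %d cells\n",
              length(x$gene_ids), length(x$cell_ids)))
  invisible(x)
}

# wrap an integrated reference back into a normalized_matrix so the next
# pairwise step can treat it as a dataset
as_normalized <- function(values, cell_meta, hvg_ids) {
  structure(list(values = values, gene_ids = rownames(values),
                 cell_ids = colnames(values), cell_meta = cell_meta,
                 provenance = list(), hvg_ids = hvg_ids),
            class = "normalized_matrix")
}

#' Integrate a list of datasets sequentially
#'
#' Datasets are merged largest-first: the largest dataset seeds the
#' reference, and each remaining dataset (in decreasing size order) is
#' embedded against the growing reference by [cca_embed()], anchored by
#' [find_anchors()], filtered by [filter_anchors()] and corrected by
#' [apply_correction()]. The merge order rule makes the result
#' deterministic; ties in size are broken by input position.
#'
#' @param datasets list of >= 2 `normalized_matrix` objects sharing the
#'   same gene set.
#' @param d CCA dimensionality.
#' @param k_anchor,k_score,min_score,k_weight anchor parameters, see the
#'   pairwise operations.
#' @return an `integrated_matrix` covering all cells, with the anchor
#'   table and merge order recorded in `correction_provenance`.
#' @export
integrate_many <- function(datasets, d = 20, k_anchor = 5, k_score = 30,
                           min_score = 0.1, k_weight = 100) {
  stopifnot(is.list(datasets), length(datasets) >= 2)
  sizes <- vapply(datasets, function(x) length(x$cell_ids), integer(1))
  ord <- order(-sizes)
  datasets <- datasets[ord]
  genes <- datasets[[1L]]$gene_ids
  for (ds in datasets[-1L])
    if (!identical(sort(ds$gene_ids), sort(genes)))
      stop("integrate_many: datasets must share the same gene set", call. = FALSE)
  ref_values <- as.matrix(datasets[[1L]]$values)
  ref_meta <- datasets[[1L]]$cell_meta
  hvg_ids <- datasets[[1L]]$hvg_ids
  anchor_tables <- list()
  for (j in seq_along(datasets)[-1L]) {
    qry <- datasets[[j]]
    qry$values <- qry$values[genes, , drop = FALSE]
    qry$gene_ids <- genes
    ref_nm <- as_normalized(ref_values, ref_meta, hvg_ids)
    e <- cca_embed(ref_nm, qry, d = min(d, ncol(ref_values) - 1L,
                                        length(qry$cell_ids) - 1L,
                                        length(genes)))
    an <- find_anchors(e, k_anchor = k_anchor)
    an <- filter_anchors(an, e, k_score = k_score, min_score = min_score)
    intm <- apply_correction(qry, ref_nm, an, e, k_weight = k_weight)
    ref_values <- intm$values
    ref_meta <- intm$cell_meta
    anchor_tables[[length(anchor_tables) + 1L]] <- an$pairs
  }
  structure(list(values = ref_values,
                 gene_ids = rownames(ref_values),
                 cell_ids = colnames(ref_values),
                 cell_meta = ref_meta,
                 hvg_ids = hvg_ids,
                 correction_provenance = list(
                   d = d, k_anchor = k_anchor, k_score = k_score,
                   min_score = min_score, k_weight = k_weight,
                   merge_order = ord),
                 anchors = do.call(rbind, anchor_tables)),
            class = "integrated_matrix")
}
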