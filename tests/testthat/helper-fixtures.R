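# Shared fixtures and independent oracles used across the suite.

# Wrap a dense genes x cells matrix as a normalized_matrix, optionally with
# metadata; bypasses the count pipeline so unit tests can feed arbitrary
# log-scale values directly.
toy_normalized <- function(values, batch = "batch1", condition = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("c%03d", seq_len(ncol(values)))
  meta <- data.frame(cell_id = colnames(values),
                     batch = rep_len(batch, ncol(values)),
                     stringsAsFactors = FALSE)
  if (!is.null(condition)) meta$condition <- rep_len(condition, ncol(values))
  structure(list(values = Matrix::Matrix(values, sparse = TRUE),
                 gene_ids = rownames(values), cell_ids = colnames(values),
                 cell_meta = meta, provenance = list(), hvg_ids = rownames(values)),
            class = "normalized_matrix")
}

# Build a ranked_genes object directly from an ordered gene vector.
toy_ranking <- function(ordered, name = "toy") {
  ranked_genes(data.frame(gene_id = ordered,
                          score = rev(seq_along(ordered)),
                          stringsAsFactors = FALSE), name)
}

# Independent brute-force Borda aggregator: explicit per-ranker point
# loop, ordering by grade with a seeded shuffle inside each tie block.
brute_force_borda <- function(orderings, tie_seed) {
  genes <- sort(orderings[[1]])
  grades <- setNames(rep(0, length(genes)), genes)
  for (og in orderings) {
    m <- length(og)
    for (pos in seq_len(m)) grades[og[pos]] <- grades[og[pos]] + (m - pos)
  }
  set.seed(tie_seed)
  prio <- sample.int(length(genes))
  list(grades = grades, ordering = genes[order(-grades, prio)])
}

# Exhaustive-partition oracle for the two-sided rank-sum p-value with
# groups of size n1 out of n1+n2 values (no ties): enumerate all
# C(n, n1) equally likely group assignments and count partitions whose
# centered rank-sum statistic is at least as extreme as observed.
exhaustive_wilcoxon_p <- function(x1, x2) {
  pooled <- c(x1, x2)
  n1 <- length(x1)
  n <- length(pooled)
  r <- rank(pooled)
  stat_obs <- abs(sum(r[seq_len(n1)]) - n1 * (n + 1) / 2)
  combos <- utils::combn(n, n1)
  stats <- apply(combos, 2, function(idx) abs(sum(r[idx]) - n1 * (n + 1) / 2))
  mean(stats >= stat_obs - 1e-9)
}

# O(n^2) mutual nearest-neighbor oracle over two embedding blocks
# (rows = cells), plain loops and full sorts.
brute_force_mnn <- function(A, B, k) {
  pairs <- NULL
  for (i in seq_len(nrow(A))) {
    di <- sqrt(colSums((t(B) - A[i, ])^2))
    nn_i <- order(di)[seq_len(k)]
    for (j in nn_i) {
      dj <- sqrt(colSums((t(A) - B[j, ])^2))
      if (i %in% order(dj)[seq_len(k)])
        pairs <- rbind(pairs, c(i, j))
    }
  }
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

# Small simulated two-batch dataset taken through QC/normalization/HVG,
# returned with per-batch splits ready for integration tests.
sim_through_hvg <- function(cfg, n_hvg = NULL, qc = c(10, 2)) {
  sim <- simulate_dataset(cfg)
  counts <- qc_filter(sim$counts, qc[1], qc[2])
  nm <- normalize_log(counts)
  if (!is.null(n_hvg)) nm <- select_hvg(nm, n_hvg)
  batches <- split(seq_along(nm$cell_ids), nm$cell_meta$batch)
  datasets <- lapply(batches, function(idx) {
    o <- nm
    o$values <- nm$values[, idx, drop = FALSE]
    o$cell_ids <- nm$cell_ids[idx]
    o$cell_meta <- nm$cell_meta[idx, , drop = FALSE]
    o
  })
  list(sim = sim, normalized = nm, datasets = datasets)
}
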