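make_pair <- function(n_genes = 40, n_a = 20, n_b = 25, seed = 1,
                      shift = 0) {
  set.seed(seed)
  shared <- matrix(rnorm(n_genes * 3), n_genes, 3)
  xa <- shared %*% matrix(rnorm(3 * n_a), 3, n_a) + rnorm(n_genes * n_a, sd = 0.3)
  xb <- shared %*% matrix(rnorm(3 * n_b), 3, n_b) + rnorm(n_genes * n_b, sd = 0.3)
  xb <- xb + shift
  rownames(xa) <- rownames(xb) <- sprintf("g%03d", seq_len(n_genes))
  colnames(xa) <- sprintf("a%03d", seq_len(n_a))
  colnames(xb) <- sprintf("b%03d", seq_len(n_b))
  list(a = toy_normalized(xa, batch = "A"), b = toy_normalized(xb, batch = "B"))
}

test_that("CCA of a dataset with itself has canonical correlations ~ 1", {
  p <- make_pair(n_a = 15, n_b = 15, seed = 2)
  e <- cca_embed(p$a, p$a, d = 5)
  expect_true(all(e$canonical_correlations >= 0.999))
})

test_that("canonical correlations are nonincreasing and in [0, 1]", {
  for (seed in 1:3) {
    p <- make_pair(seed = seed)
    e <- cca_embed(p$a, p$b, d = 8)
    cc <- e$canonical_correlations
    expect_true(all(diff(cc) <= 1e-12))
    expect_true(all(cc >= 0 & cc <= 1 + 1e-12))
  }
})

test_that("singular values match a dense eigendecomposition oracle", {
  p <- make_pair(n_genes = 30, n_a = 20, n_b = 25, seed = 7)
  e <- cca_embed(p$a, p$b, d = 10)
  # independent oracle: eigenvalues of K'K where K is the cross-product of
  # the standardized matrices
  std <- function(m) {
    x <- as.matrix(m$values)
    t(scale(t(x)))
  }
  K <- crossprod(std(p$a), std(p$b))
  ev <- sqrt(sort(eigen(crossprod(K), symmetric = TRUE)$values,
                  decreasing = TRUE)[1:10])
  expect_equal(sort(e$singular_values, decreasing = TRUE), ev,
               tolerance = 1e-8)
})

test_that("degenerate inputs are handled", {
  p <- make_pair(n_a = 10, n_b = 10, seed = 3)
  expect_error(cca_embed(p$a, p$b, d = 11), "exceeds the rank bound")
  flat_a <- p$a
  flat_b <- p$b
  flat_a$values[1, ] <- 0
  flat_b$values[1, ] <- 0
  expect_warning(cca_embed(flat_a, flat_b, d = 5), "zero variance")
})

test_that("anchors on duplicated data form a perfect matching", {
  p <- make_pair(n_a = 30, n_b = 30, seed = 4)
  e <- cca_embed(p$a, p$a, d = 5)
  an <- find_anchors(e, k_anchor = 3)
  self_pairs <- an$pairs[an$pairs$idx_a == an$pairs$idx_b, ]
  expect_identical(nrow(self_pairs), 30L)
  expect_true(all(an$pairs$score == 1))
})

test_that("anchor sets are symmetric under dataset swap", {
  p <- make_pair(seed = 5)
  e_ab <- cca_embed(p$a, p$b, d = 6)
  e_ba <- cca_embed(p$b, p$a, d = 6)
  an_ab <- find_anchors(e_ab, k_anchor = 4)
  an_ba <- find_anchors(e_ba, k_anchor = 4)
  key_ab <- paste(an_ab$pairs$cell_a, an_ab$pairs$cell_b)
  key_ba <- paste(an_ba$pairs$cell_b, an_ba$pairs$cell_a)
  expect_setequal(key_ab, key_ba)
})

test_that("anchor search agrees with the exhaustive mutual-NN oracle", {
  p <- make_pair(n_genes = 30, n_a = 40, n_b = 40, seed = 6)
  e <- cca_embed(p$a, p$b, d = 6)
  an <- find_anchors(e, k_anchor = 5)
  A <- e$loadings_a / sqrt(rowSums(e$loadings_a^2))
  B <- e$loadings_b / sqrt(rowSums(e$loadings_b^2))
  oracle <- brute_force_mnn(A, B, 5)
  expect_equal(unname(as.matrix(an$pairs[, c("idx_a", "idx_b")])),
               unname(oracle))
  expect_error(find_anchors(e, k_anchor = 41), "exceeds dataset size")
})

test_that("anchor filtering keeps duplicates at score 1 and min_score 0 is identity", {
  p <- make_pair(n_a = 30, n_b = 30, seed = 8)
  e <- cca_embed(p$a, p$a, d = 5)
  an <- find_anchors(e, k_anchor = 3)
  filt <- filter_anchors(an, e, k_score = 10, min_score = 0.99)
  self_pairs <- filt$pairs[filt$pairs$idx_a == filt$pairs$idx_b, ]
  expect_identical(nrow(self_pairs), 30L)
  expect_true(all(self_pairs$score == 1))

  p2 <- make_pair(seed = 9)
  e2 <- cca_embed(p2$a, p2$b, d = 6)
  an2 <- find_anchors(e2, k_anchor = 4)
  filt0 <- filter_anchors(an2, e2, k_score = 10, min_score = 0)
  expect_identical(filt0$pairs[, c("cell_a", "cell_b")],
                   an2$pairs[, c("cell_a", "cell_b")])
})

test_that("an injected mismatched anchor gets the lowest score and is dropped", {
  p <- make_pair(n_genes = 50, n_a = 60, n_b = 60, seed = 10)
  e <- cca_embed(p$a, p$b, d = 6)
  an <- find_anchors(e, k_anchor = 5)
  A <- e$loadings_a / sqrt(rowSums(e$loadings_a^2))
  B <- e$loadings_b / sqrt(rowSums(e$loadings_b^2))
  # inject the worst possible pair: the two cross-dataset cells farthest apart
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  worst <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  bad <- data.frame(cell_a = e$cell_ids_a[worst[1]],
                    cell_b = e$cell_ids_b[worst[2]],
                    idx_a = as.integer(worst[1]), idx_b = as.integer(worst[2]),
                    score = 1)
  an$pairs <- rbind(an$pairs, bad)
  filt <- filter_anchors(an, e, k_score = 20, min_score = 0.1)
  kept <- paste(filt$pairs$idx_a, filt$pairs$idx_b)
  expect_false(paste(worst[1], worst[2]) %in% kept)
})

test_that("a constant batch shift is removed exactly by correction", {
  p <- make_pair(n_genes = 30, n_a = 25, n_b = 25, seed = 11)
  ref <- p$a
  qry <- ref
  qry$values <- ref$values + 1.7
  qry$gene_ids <- ref$gene_ids
  qry$cell_ids <- paste0("q_", ref$cell_ids)
  colnames(qry$values) <- qry$cell_ids
  qry$cell_meta$cell_id <- qry$cell_ids
  qry$cell_meta$batch <- "Q"
  e <- cca_embed(ref, qry, d = 5)
  an <- find_anchors(e, k_anchor = 1)
  true_pairs <- an$pairs[an$pairs$idx_a == an$pairs$idx_b, ]
  an$pairs <- true_pairs
  out <- apply_correction(qry, ref, an, e, k_weight = 10)
  corrected <- out$values[, qry$cell_ids]
  expect_lt(max(abs(corrected - as.matrix(ref$values))), 1e-6)
  # reference cells are untouched
  expect_equal(out$values[, ref$cell_ids], as.matrix(ref$values))
})

test_that("identical datasets yield near-zero correction", {
  p <- make_pair(n_a = 20, n_b = 20, seed = 12)
  qry <- p$a
  qry$cell_ids <- paste0("q_", qry$cell_ids)
  colnames(qry$values) <- qry$cell_ids
  qry$cell_meta$cell_id <- qry$cell_ids
  # k_anchor = 1 pairs every cell with its exact duplicate, so all
  # correction vectors are identically zero
  e <- cca_embed(p$a, qry, d = 5)
  an <- find_anchors(e, k_anchor = 1)
  out <- suppressWarnings(apply_correction(qry, p$a, an, e, k_weight = 100))
  expect_lt(max(abs(out$values[, qry$cell_ids] - as.matrix(p$a$values))), 1e-6)
})

test_that("correction reduces the batch silhouette on simulated batch effects", {
  cfg <- simulation_config(n_genes = 300, n_cells_per_batch = c(200, 200),
                           n_marker_genes = 0, condition_effect = 0,
                           batch_effect_sd = 0.5, seed = 13)
  prep <- sim_through_hvg(cfg, n_hvg = 200)
  merged <- as.matrix(prep$normalized$values)
  sil_before <- batch_silhouette(merged, prep$normalized$cell_meta$batch,
                                 max_cells = 300)
  im <- integrate_many(prep$datasets, d = 15, k_weight = 50)
  sil_after <- batch_silhouette(im$values,
                                im$cell_meta$batch[match(im$cell_ids,
                                                         colnames(im$values))],
                                max_cells = 300)
  expect_lt(sil_after, sil_before)
})

test_that("integrate_many of two datasets equals the pairwise path", {
  p <- make_pair(n_genes = 40, n_a = 30, n_b = 25, seed = 14)
  im <- integrate_many(list(p$a, p$b), d = 8, k_anchor = 5, k_score = 10,
                       min_score = 0.1, k_weight = 20)
  e <- cca_embed(p$a, p$b, d = 8)
  an <- filter_anchors(find_anchors(e, 5), e, k_score = 10, min_score = 0.1)
  pw <- apply_correction(p$b, p$a, an, e, k_weight = 20)
  expect_equal(im$values, pw$values)
})

test_that("three identical datasets integrate to the concatenated input", {
  p <- make_pair(n_a = 20, n_b = 20, seed = 15)
  mk <- function(tag) {
    o <- p$a
    o$cell_ids <- paste0(tag, o$cell_ids)
    colnames(o$values) <- o$cell_ids
    o$cell_meta$cell_id <- o$cell_ids
    o$cell_meta$batch <- tag
    o
  }
  ds <- list(mk("x_"), mk("y_"), mk("z_"))
  im <- suppressWarnings(integrate_many(ds, d = 5, k_anchor = 1,
                                        k_score = 5, k_weight = 20))
  ref <- as.matrix(p$a$values)
  for (tag in c("x_", "y_", "z_")) {
    block <- im$values[, paste0(tag, p$a$cell_ids)]
    expect_lt(max(abs(block - ref)), 1e-6)
  }
})

test_that("a many-batch cohort integrates and reduces batch structure", {
  cfg <- simulation_config(n_genes = 200, n_cells_per_batch = rep(60, 14),
                           n_batches = 14, n_marker_genes = 0,
                           condition_effect = 0, batch_effect_sd = 0.5,
                           seed = 16)
  prep <- sim_through_hvg(cfg, n_hvg = 150, qc = c(5, 2))
  merged <- as.matrix(prep$normalized$values)
  sil_before <- batch_silhouette(merged, prep$normalized$cell_meta$batch,
                                 max_cells = 400)
  im <- integrate_many(prep$datasets, d = 10, k_anchor = 3, k_score = 15,
                       k_weight = 30)
  meta_batch <- im$cell_meta$batch[match(colnames(im$values), im$cell_meta$cell_id)]
  sil_after <- batch_silhouette(im$values, meta_batch, max_cells = 400)
  expect_lt(sil_after, sil_before)
})
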