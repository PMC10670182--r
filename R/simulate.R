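#' Configuration for the multi-batch two-condition count simulator
#'
#' Defines a synthetic scRNA-seq study: several batches of cells, two
#' biological conditions mixed within every batch, a minority set of
#' marker genes carrying a known log2 fold change between conditions,
#' and per-gene per-batch multiplicative distortions standing in for
#' technical batch effects.
#'
#' Counts are negative binomial with
#' \deqn{\mu_{gc} = \mathrm{base}_g \cdot 2^{\mathrm{lfc}_g \cdot [c \in \mathrm{disease}]} \cdot f_{g,b(c)}}
#' where the baseline means are log-normal across genes and the batch
#' factors \eqn{f_{g,b}} are log-normal with log-scale standard deviation
#' `batch_effect_sd`.
#'
#' @param n_genes number of genes.
#' @param n_cells_per_batch integer vector of cells per batch (recycled to
#'   `n_batches`).
#' @param n_batches number of batches (>= 2).
#' @param n_marker_genes number of condition-discriminative genes.
#' @param condition_effect log2 fold change of the markers in the disease
#'   condition; scalar or one value per marker (signs allowed, so a mix of
#'   up- and downregulated markers can be planted).
#' @param batch_effect_sd standard deviation (natural-log scale) of the
#'   per-gene per-batch multiplicative distortion; 0 disables batch effects.
#' @param dispersion negative-binomial size (inverse dispersion); scalar or
#'   per gene. Larger means closer to Poisson.
#' @param base_mean_meanlog,base_mean_sdlog parameters of the log-normal
#'   distribution of per-gene baseline means.
#' @param condition_fraction fraction of each batch's cells in the second
#'   (disease) condition.
#' @param condition_column name of the metadata column carrying the
#'   condition label.
#' @param condition_levels two labels, control first.
#' @param seed integer seed; generation is a pure function of the config.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              n_cells_per_batch = c(1000, 1000),
                              n_batches = length(n_cells_per_batch),
                              n_marker_genes = 100,
                              condition_effect = 1.5,
                              batch_effect_sd = 0.5,
                              dispersion = 2,
                              base_mean_meanlog = log(0.5),
                              base_mean_sdlog = 1,
                              condition_fraction = 0.5,
                              condition_column = "condition",
                              condition_levels = c("control", "disease"),
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_cells_per_batch = as.integer(rep_len(n_cells_per_batch, n_batches)),
              n_batches = as.integer(n_batches),
              n_marker_genes = as.integer(n_marker_genes),
              condition_effect = as.numeric(condition_effect),
              batch_effect_sd = as.numeric(batch_effect_sd),
              dispersion = as.numeric(dispersion),
              base_mean_meanlog = as.numeric(base_mean_meanlog),
              base_mean_sdlog = as.numeric(base_mean_sdlog),
              condition_fraction = as.numeric(condition_fraction),
              condition_column = condition_column,
              condition_levels = condition_levels,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_genes < 1L)
    stop("configuration error: n_genes must be a positive integer", call. = FALSE)
  if (cfg$n_batches < 2L)
    stop("configuration error: n_batches must be >= 2", call. = FALSE)
  if (any(cfg$n_cells_per_batch < 1L))
    stop("configuration error: n_cells_per_batch must be positive", call. = FALSE)
  if (cfg$n_marker_genes < 0L || cfg$n_marker_genes > cfg$n_genes)
    stop("configuration error: n_marker_genes must lie in [0, n_genes]", call. = FALSE)
  if (cfg$batch_effect_sd < 0)
    stop("configuration error: batch_effect_sd must be nonnegative", call. = FALSE)
  if (any(cfg$dispersion <= 0))
    stop("configuration error: dispersion must be positive", call. = FALSE)
  if (cfg$condition_fraction < 0 || cfg$condition_fraction > 1)
    stop("configuration error: condition_fraction must lie in [0, 1]", call. = FALSE)
  if (length(cfg$condition_levels) != 2L)
    stop("configuration error: condition_levels must have exactly two labels", call. = FALSE)
  invisible(cfg)
}

#' Simulate a multi-batch two-condition count dataset with ground truth
#'
#' Draws negative-binomial counts under the model described in
#' [simulation_config()] and returns both the count matrix (with per-cell
#' batch/condition metadata) and the planted ground truth: the marker gene
#' set, every gene's true log2 fold change, and the batch distortion
#' factors. Generation is deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @return a list with elements `counts` (a `count_matrix`) and `truth`
#'   (a `ground_truth`).
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  validate_simulation_config(config)
  G <- config$n_genes
  B <- config$n_batches
  set.seed(config$seed)

  gene_ids <- sprintf("gene%05d", seq_len(G))
  base_mean <- rlnorm(G, config$base_mean_meanlog, config$base_mean_sdlog)

  lfc <- setNames(rep(0, G), gene_ids)
  markers <- character(0)
  if (config$n_marker_genes > 0L) {
    marker_idx <- sort(sample.int(G, config$n_marker_genes))
    effects <- rep_len(config$condition_effect, config$n_marker_genes)
    lfc[marker_idx] <- effects
    markers <- gene_ids[marker_idx][effects != 0]
  }

  batch_factors <- matrix(1, G, B,
                          dimnames = list(gene_ids, sprintf("batch%d", seq_len(B))))
  if (config$batch_effect_sd > 0)
    batch_factors[] <- exp(rnorm(G * B, 0, config$batch_effect_sd))

  size <- rep_len(config$dispersion, G)
  blocks <- vector("list", B)
  meta_list <- vector("list", B)
  for (b in seq_len(B)) {
    n_b <- config$n_cells_per_batch[b]
    n_dis <- round(config$condition_fraction * n_b)
    cond <- sample(rep(config$condition_levels, c(n_b - n_dis, n_dis)))
    is_dis <- cond == config$condition_levels[2L]
    mu <- (base_mean * batch_factors[, b]) %o% rep(1, n_b)
    if (any(lfc != 0))
      mu <- mu * 2^(lfc %o% as.numeric(is_dis))
    counts_b <- matrix(rnbinom(G * n_b, mu = mu, size = size), G, n_b)
    blocks[[b]] <- counts_b
    meta_list[[b]] <- data.frame(
      cell_id = sprintf("batch%d_cell%05d", b, seq_len(n_b)),
      batch = sprintf("batch%d", b),
      condition = cond,
      stringsAsFactors = FALSE)
  }
  values <- do.call(cbind, blocks)
  meta <- do.call(rbind, meta_list)
  rownames(values) <- gene_ids
  colnames(values) <- meta$cell_id
  if (config$condition_column != "condition")
    names(meta)[names(meta) == "condition"] <- config$condition_column

  counts <- count_matrix(values, meta)
  truth <- structure(list(marker_gene_ids = markers,
                          per_gene_log2fc = lfc,
                          batch_factors = batch_factors),
                     class = "ground_truth")
  list(counts = counts, truth = truth)
}

#' Write a count dataset as a 10x-style MTX triplet
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and a
#' `cell_metadata.tsv` (barcode, batch, condition, any extra columns) to
#' a directory, plus the simulation config as `config.json` when given.
#'
#' @param m a `count_matrix`.
#' @param dir output directory (created if missing).
#' @param config optional [simulation_config()] to record alongside.
#' @return `dir`, invisibly.
#' @export
write_mtx_dataset <- function(m, dir, config = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(m$values, file.path(dir, "matrix.mtx"))
  writeLines(m$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(m$cell_ids, file.path(dir, "barcodes.tsv"))
  meta <- m$cell_meta
  names(meta)[names(meta) == "cell_id"] <- "barcode"
  utils::write.table(meta, file.path(dir, "cell_metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(config))
    jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("simulation_config: %d genes, %d batches (%s cells), %d markers\n",
              x$n_genes, x$n_batches,
              paste(x$n_cells_per_batch, collapse = "+"), x$n_marker_genes))
  cat(sprintf("  effect (log2) %s | batch sd %.3g | dispersion %.3g | seed %d\n",
              paste(unique(x$condition_effect), collapse = ","),
              x$batch_effect_sd, x$dispersion[1], x$seed))
  invisible(x)
}
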