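#' Count matrix container
#'
#' Genes x cells nonnegative integer counts stored sparse, with per-cell
#' metadata carrying at least a batch label.
#'
#' @param values genes x cells matrix (dense or sparse) of nonnegative
#'   counts with row and column names.
#' @param cell_meta data.frame with a `cell_id` column matching the matrix
#'   columns plus at least a `batch` column.
#' @return an object of class `count_matrix` with fields `values`,
#'   `gene_ids`, `cell_ids`, `cell_meta`.
#' @export
count_matrix <- function(values, cell_meta) {
  if (!methods::is(values, "Matrix"))
    values <- Matrix::Matrix(values, sparse = TRUE)
  values <- as(as(as(values, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  gene_ids <- rownames(values)
  cell_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("count_matrix: values must carry gene and cell names", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("count_matrix: duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("count_matrix: duplicate cell identifiers", call. = FALSE)
  if (min(values) < 0)
    stop("count_matrix: counts must be nonnegative", call. = FALSE)
  if (!is.data.frame(cell_meta) || is.null(cell_meta$cell_id))
    stop("count_matrix: cell_meta must be a data.frame with a cell_id column",
         call. = FALSE)
  if (anyDuplicated(cell_meta$cell_id))
    stop("count_matrix: duplicate cell_id in metadata", call. = FALSE)
  if (!setequal(cell_meta$cell_id, cell_ids))
    stop("count_matrix: metadata cell ids do not match matrix columns",
         call. = FALSE)
  if (is.null(cell_meta$batch))
    stop("count_matrix: every cell needs a batch label", call. = FALSE)
  cell_meta <- cell_meta[match(cell_ids, cell_meta$cell_id), , drop = FALSE]
  rownames(cell_meta) <- NULL
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells, %d batch(es)\n",
              length(x$gene_ids), length(x$cell_ids),
              length(unique(x$cell_meta$batch))))
  invisible(x)
}

#' Read a count matrix from disk
#'
#' Supports a 10x-style MTX triplet directory (`matrix.mtx`, `genes.tsv`,
#' `barcodes.tsv`, `cell_metadata.tsv`) or a dense CSV (first column gene
#' id, remaining columns cells) with a metadata table alongside.
#'
#' @param path directory (mtx_triplet) or CSV file (csv).
#' @param format one of `"mtx_triplet"`, `"csv"`.
#' @param metadata path to the cell metadata table; defaults to
#'   `cell_metadata.tsv` next to the input.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, format = c("mtx_triplet", "csv"),
                        metadata = NULL) {
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    mtx_file <- file.path(path, "matrix.mtx")
    genes_file <- file.path(path, "genes.tsv")
    bc_file <- file.path(path, "barcodes.tsv")
    meta_file <- if (is.null(metadata)) file.path(path, "cell_metadata.tsv") else metadata
    for (f in c(mtx_file, genes_file, bc_file, meta_file))
      if (!file.exists(f))
        stop(sprintf("format error: missing file '%s'", f), call. = FALSE)
    values <- as(Matrix::readMM(mtx_file), "CsparseMatrix")
    genes <- readLines(genes_file)
    genes <- vapply(strsplit(genes, "\t", fixed = TRUE), `[`, "", 1L)
    barcodes <- readLines(bc_file)
    if (anyDuplicated(genes))
      stop(sprintf("format error: duplicate gene id in '%s' (first: '%s')",
                   genes_file, genes[duplicated(genes)][1]), call. = FALSE)
    if (anyDuplicated(barcodes))
      stop(sprintf("format error: duplicate barcode in '%s' (first: '%s')",
                   bc_file, barcodes[duplicated(barcodes)][1]), call. = FALSE)
    if (nrow(values) != length(genes))
      stop(sprintf("format error: '%s' has %d rows but '%s' lists %d genes",
                   mtx_file, nrow(values), genes_file, length(genes)),
           call. = FALSE)
    if (ncol(values) != length(barcodes))
      stop(sprintf("format error: '%s' has %d columns but '%s' lists %d barcodes",
                   mtx_file, ncol(values), bc_file, length(barcodes)),
           call. = FALSE)
    dimnames(values) <- list(genes, barcodes)
    meta <- utils::read.delim(meta_file, stringsAsFactors = FALSE)
  } else {
    if (!file.exists(path))
      stop(sprintf("format error: missing file '%s'", path), call. = FALSE)
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    genes <- df[[1L]]
    if (anyDuplicated(genes))
      stop(sprintf("format error: duplicate gene id in '%s' (first: '%s')",
                   path, genes[duplicated(genes)][1]), call. = FALSE)
    values <- as.matrix(df[, -1L, drop = FALSE])
    rownames(values) <- genes
    meta_file <- if (is.null(metadata))
      file.path(dirname(path), "cell_metadata.tsv") else metadata
    if (!file.exists(meta_file))
      stop(sprintf("format error: missing metadata file '%s'", meta_file),
           call. = FALSE)
    meta <- utils::read.delim(meta_file, stringsAsFactors = FALSE)
  }
  if (is.null(meta$barcode))
    stop(sprintf("format error: '%s' lacks a 'barcode' column", meta_file),
         call. = FALSE)
  missing_bc <- setdiff(colnames(values), meta$barcode)
  if (length(missing_bc) > 0)
    stop(sprintf("format error: '%s' missing metadata for barcode '%s'",
                 meta_file, missing_bc[1]), call. = FALSE)
  names(meta)[names(meta) == "barcode"] <- "cell_id"
  meta <- meta[match(colnames(values), meta$cell_id), , drop = FALSE]
  count_matrix(values, meta)
}

#' Quality-control filtering of cells then genes
#'
#' Removes cells detecting fewer than `min_genes_per_cell` genes first,
#' then genes detected in fewer than `min_cells_per_gene` of the
#' remaining cells. The order of the two passes is fixed (cells first),
#' which makes the operation idempotent.
#'
#' Defaults follow common single-cell QC practice (200 genes per cell,
#' 3 cells per gene).
#'
#' @param m a [count_matrix()].
#' @param min_genes_per_cell,min_cells_per_gene nonnegative thresholds.
#' @return filtered `count_matrix`.
#' @export
qc_filter <- function(m, min_genes_per_cell = 200, min_cells_per_gene = 3) {
  stopifnot(inherits(m, "count_matrix"),
            min_genes_per_cell >= 0, min_cells_per_gene >= 0)
  detected <- m$values > 0
  keep_cells <- Matrix::colSums(detected) >= min_genes_per_cell
  if (!any(keep_cells))
    stop("empty after QC: no cell detects at least min_genes_per_cell genes",
         call. = FALSE)
  values <- m$values[, keep_cells, drop = FALSE]
  keep_genes <- Matrix::rowSums(values > 0) >= min_cells_per_gene
  if (!any(keep_genes))
    stop("empty after QC: no gene is detected in at least min_cells_per_gene cells",
         call. = FALSE)
  values <- values[keep_genes, , drop = FALSE]
  count_matrix(values, m$cell_meta[keep_cells, , drop = FALSE])
}

#' Library-size normalization and log transform
#'
#' Scales every cell to `scale_target` total counts, then applies
#' `log(pseudocount + x)`. With the default pseudocount of 1 the
#' transform is `log1p`, and `colSums(expm1(values))` equals
#' `scale_target` for every cell.
#'
#' @param m a [count_matrix()].
#' @param scale_target per-cell total after scaling (default 10,000).
#' @param pseudocount added before the log (default 1).
#' @return a `normalized_matrix` (fields `values`, `gene_ids`, `cell_ids`,
#'   `cell_meta`, `provenance`, `hvg_ids`).
#' @export
normalize_log <- function(m, scale_target = 1e4, pseudocount = 1) {
  stopifnot(inherits(m, "count_matrix"), scale_target > 0, pseudocount > 0)
  totals <- Matrix::colSums(m$values)
  if (any(totals == 0))
    stop(sprintf("cell '%s' has zero total counts; QC should have removed it",
                 m$cell_ids[which(totals == 0)[1]]), call. = FALSE)
  scaled <- m$values %*% Matrix::Diagonal(x = scale_target / totals)
  dimnames(scaled) <- dimnames(m$values)
  if (pseudocount == 1) {
    values <- scaled
    values@x <- log1p(values@x)
  } else {
    values <- as(log(as.matrix(scaled) + pseudocount), "CsparseMatrix")
  }
  structure(list(values = values, gene_ids = m$gene_ids, cell_ids = m$cell_ids,
                 cell_meta = m$cell_meta,
                 provenance = list(scale_target = scale_target,
                                   pseudocount = pseudocount),
                 hvg_ids = NULL),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d cells%s\n",
              length(x$gene_ids), length(x$cell_ids),
              if (is.null(x$hvg_ids)) ""
              else sprintf(" (%d HVGs)", length(x$hvg_ids))))
  invisible(x)
}

#' Select highly variable genes
#'
#' Ranks genes by a variance-stabilized statistic: a loess trend of
#' log10 variance against log10 mean is fitted across genes, expression
#' is standardized by the trend-expected standard deviation, standardized
#' values are clipped at `sqrt(n_cells)`, and genes are ranked by the
#' variance of the clipped standardized values (`method = "vst"`). A
#' plain dispersion ranking (variance/mean) is available as
#' `method = "dispersion"`. Ties are broken by gene identifier, so the
#' ranking is deterministic.
#'
#' @param m a `normalized_matrix`.
#' @param n number of genes to keep (default 2000).
#' @param method `"vst"` (default) or `"dispersion"`.
#' @param loess_span span of the mean-variance trend fit.
#' @return `m` restricted to the selected genes, with `hvg_ids` set in
#'   ranking order.
#' @export
select_hvg <- function(m, n = 2000, method = c("vst", "dispersion"),
                       loess_span = 0.3) {
  stopifnot(inherits(m, "normalized_matrix"))
  method <- match.arg(method)
  G <- length(m$gene_ids)
  if (n > G)
    stop(sprintf("cannot select %d HVGs from %d genes", n, G), call. = FALSE)
  x <- as.matrix(m$values)
  mu <- rowMeans(x)
  v <- row_vars(x)
  if (method == "vst") {
    usable <- v > 0 & mu > 0
    stat <- rep(0, G)
    if (sum(usable) > 1L) {
      fit <- loess(log10(v[usable]) ~ log10(mu[usable]), span = loess_span,
                   degree = 2)
      sd_expected <- sqrt(10^predict(fit))
      clip <- sqrt(ncol(x))
      z <- (x[usable, , drop = FALSE] - mu[usable]) / sd_expected
      z[z > clip] <- clip
      z[z < -clip] <- -clip
      stat[usable] <- row_vars(z)
    }
  } else {
    stat <- ifelse(mu > 0, v / mu, 0)
  }
  ord <- order(-stat, m$gene_ids)
  hvg <- m$gene_ids[ord][seq_len(n)]
  out <- m
  out$values <- m$values[hvg, , drop = FALSE]
  out$gene_ids <- hvg
  out$hvg_ids <- hvg
  out$provenance <- c(m$provenance,
                      list(hvg_method = method, hvg_n = n))
  out
}
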