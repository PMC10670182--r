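#' Configuration for one end-to-end case study
#'
#' One object drives the whole pipeline: simulate (or read) counts, QC,
#' normalize, select HVGs, integrate the batches, rank genes by the
#' Wilcoxon and boosted-tree rankers on the contrast of interest, fuse
#' by Borda, cut the top-k set and evaluate. Every default is echoed
#' into the run manifest so there are no hidden parameters.
#'
#' @param mode `"synthetic"` (simulate) or `"real"` (read from disk).
#' @param simulation a [simulation_config()] (synthetic mode).
#' @param input path for [read_counts()] (real mode).
#' @param input_format format for [read_counts()].
#' @param contrast metadata column defining the two groups (e.g.
#'   `"condition"`, or `"region"` for a region contrast); must have
#'   exactly two levels after filtering.
#' @param qc list of [qc_filter()] thresholds.
#' @param normalize list of [normalize_log()] parameters.
#' @param hvg list of [select_hvg()] parameters (`n`, `method`).
#' @param integration list of [integrate_many()] parameters.
#' @param boosting list of [gain_rank()] parameters (`nrounds`, `seed`).
#' @param tie_seed Borda tie-break seed.
#' @param top_k consensus cut (default 100).
#' @param thresholds regulation-category thresholds for [categorize()].
#' @param out_dir run output directory.
#' @return object of class `case_study_config`.
#' @export
case_study_config <- function(mode = c("synthetic", "real"),
                              simulation = NULL,
                              input = NULL,
                              input_format = "mtx_triplet",
                              contrast = "condition",
                              qc = list(min_genes_per_cell = 200,
                                        min_cells_per_gene = 3),
                              normalize = list(scale_target = 1e4,
                                               pseudocount = 1),
                              hvg = list(n = 2000, method = "vst"),
                              integration = list(d = 20, k_anchor = 5,
                                                 k_score = 30,
                                                 min_score = 0.1,
                                                 k_weight = 100),
                              boosting = list(nrounds = 100, seed = 0L),
                              tie_seed = 0L,
                              top_k = 100,
                              thresholds = c(0.5, 1.5),
                              out_dir = tempfile("case_study_")) {
  mode <- match.arg(mode)
  if (mode == "synthetic" && is.null(simulation))
    stop("config error: synthetic mode needs a simulation config", call. = FALSE)
  if (mode == "real" && is.null(input))
    stop("config error: real mode needs an input path", call. = FALSE)
  structure(list(mode = mode, simulation = simulation, input = input,
                 input_format = input_format, contrast = contrast,
                 qc = qc, normalize = normalize, hvg = hvg,
                 integration = integration, boosting = boosting,
                 tie_seed = as.integer(tie_seed), top_k = as.integer(top_k),
                 thresholds = thresholds, out_dir = out_dir),
            class = "case_study_config")
}

manifest_params <- function(cfg) {
  p <- unclass(cfg)
  if (!is.null(p$simulation)) p$simulation <- unclass(p$simulation)
  p
}

#' Run one case study end to end
#'
#' Executes simulate-or-read, QC, normalization, HVG selection,
#' per-batch split, CCA/anchor integration, the two rankers, Borda
#' consensus, the top-k cut and evaluation, writing every stage output
#' plus a manifest (parameters, seeds, merge order, per-stage timings
#' and MD5 checksums of every artifact) into `cfg$out_dir`. A stage
#' failure aborts with the stage name after persisting the partial
#' manifest. Rerunning with the same config reproduces identical CSVs.
#'
#' @param cfg a [case_study_config()].
#' @return (invisibly) a list with the stage objects: `counts`, `truth`,
#'   `integrated`, `rankings`, `consensus`, `top_genes`, `log2fc`,
#'   `categories`, `report`, `out_dir`.
#' @export
run_case_study <- function(cfg) {
  stopifnot(inherits(cfg, "case_study_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "scborda",
                   version = as.character(utils::packageVersion("scborda")),
                   r_version = R.version.string,
                   params = manifest_params(cfg),
                   stages = list())
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  persist <- function() jsonlite::write_json(manifest, manifest_path,
                                             auto_unbox = TRUE, digits = NA,
                                             pretty = TRUE, force = TRUE)
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e) {
      manifest$error <<- list(stage = name, message = conditionMessage(e))
      persist()
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      elapsed_sec = round(proc.time()[["elapsed"]] - t0, 3))
    out
  }

  loaded <- run_stage("load", function() {
    if (cfg$mode == "synthetic") simulate_dataset(cfg$simulation)
    else list(counts = read_counts(cfg$input, cfg$input_format), truth = NULL)
  })
  counts <- loaded$counts
  truth <- loaded$truth

  counts <- run_stage("qc", function()
    qc_filter(counts, cfg$qc$min_genes_per_cell, cfg$qc$min_cells_per_gene))

  norm <- run_stage("normalize", function()
    normalize_log(counts, cfg$normalize$scale_target, cfg$normalize$pseudocount))

  norm <- run_stage("hvg", function()
    select_hvg(norm, n = min(cfg$hvg$n, length(norm$gene_ids)),
               method = cfg$hvg$method))

  labels_all <- run_stage("contrast", function() {
    col <- norm$cell_meta[[cfg$contrast]]
    if (is.null(col))
      stop(sprintf("config error: contrast column '%s' not found", cfg$contrast))
    col <- droplevels(as.factor(col))
    if (nlevels(col) != 2L)
      stop(sprintf("config error: contrast column '%s' has %d levels (need exactly 2)",
                   cfg$contrast, nlevels(col)))
    col
  })

  integrated <- run_stage("integrate", function() {
    batches <- split(seq_along(norm$cell_ids), norm$cell_meta$batch)
    if (length(batches) < 2L)
      stop("config error: integration needs at least two batches")
    datasets <- lapply(batches, function(idx) {
      out <- norm
      out$values <- norm$values[, idx, drop = FALSE]
      out$cell_ids <- norm$cell_ids[idx]
      out$cell_meta <- norm$cell_meta[idx, , drop = FALSE]
      out
    })
    do.call(integrate_many, c(list(datasets = datasets), cfg$integration))
  })
  labels <- labels_all[match(integrated$cell_ids, norm$cell_ids)]

  rk_w <- run_stage("rank_wilcoxon", function()
    wilcoxon_rank(integrated, labels))
  rk_g <- run_stage("rank_gain", function()
    gain_rank(integrated, labels, nrounds = cfg$boosting$nrounds,
              seed = cfg$boosting$seed))

  consensus <- run_stage("consensus", function()
    borda_aggregate(list(rk_w, rk_g), tie_seed = cfg$tie_seed))
  top_genes <- run_stage("select", function()
    select_top_k(consensus, cfg$top_k))

  eval_out <- run_stage("evaluate", function() {
    lfc <- compute_log2fc(integrated, labels)
    cats <- categorize(lfc[top_genes], cfg$thresholds)
    report <- if (!is.null(truth))
      recovery_report(top_genes, truth, consensus,
                      rankings = list(rk_w, rk_g))
    else NULL
    list(log2fc = lfc, categories = cats, report = report)
  })

  run_stage("report", function() {
    write_ranking_csv(rk_w, file.path(cfg$out_dir, "ranking_wilcoxon.csv"))
    write_ranking_csv(rk_g, file.path(cfg$out_dir, "ranking_gain.csv"))
    write_consensus_csv(consensus, file.path(cfg$out_dir, "consensus.csv"))
    writeLines(top_genes, file.path(cfg$out_dir, "top_genes.txt"))
    if (!is.null(integrated$anchors))
      utils::write.table(
        integrated$anchors[, c("cell_a", "cell_b", "score")],
        file.path(cfg$out_dir, "anchors.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    render_heatmap(eval_out$log2fc[top_genes], eval_out$categories,
                   file.path(cfg$out_dir, "top_genes"),
                   consensus_rank = setNames(
                     match(top_genes, consensus$ordering), top_genes))
    if (!is.null(eval_out$report)) {
      rep <- eval_out$report
      jsonlite::write_json(
        list(precision = rep$precision, recall = rep$recall, f1 = rep$f1,
             n_selected = rep$n_selected, n_markers = rep$n_markers,
             per_ranker_recall = as.list(rep$per_ranker_recall)),
        file.path(cfg$out_dir, "recovery.json"),
        auto_unbox = TRUE, digits = NA)
    }
    invisible(NULL)
  })

  artifacts <- list.files(cfg$out_dir, full.names = TRUE)
  artifacts <- artifacts[basename(artifacts) != "manifest.json"]
  manifest$checksums <- as.list(tools::md5sum(artifacts))
  names(manifest$checksums) <- basename(artifacts)
  persist()

  invisible(list(counts = counts, truth = truth, integrated = integrated,
                 rankings = list(wilcoxon = rk_w, gain = rk_g),
                 consensus = consensus, top_genes = top_genes,
                 log2fc = eval_out$log2fc, categories = eval_out$categories,
                 report = eval_out$report, out_dir = cfg$out_dir))
}
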