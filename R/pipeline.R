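#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end run. All randomness flows from the
#' single `seed`, split deterministically per stage, so an identical config
#' yields byte-identical probability/latent/cluster artifacts.
#'
#' @param input path to an h5ad file or MTX directory; `NULL` when the
#'   expression matrix is passed to [run_pipeline()] directly.
#' @param format input format for [load_dataset()].
#' @param label_key condition-label key.
#' @param preprocess a [preprocess_config()], or `NULL` to skip preprocessing
#'   (input already normalized).
#' @param k kNN neighbors.
#' @param n_pcs principal components for graph construction.
#' @param h GCN latent dimension.
#' @param budget_per_condition labeled training cells per condition (count,
#'   or fraction such as 0.03).
#' @param val_fraction validation share of the non-training cells.
#' @param max_epochs,patience,learning_rate,weight_decay training controls,
#'   see [train_config()].
#' @param threshold probability cutoff for condition assignment.
#' @param k_clusters k for latent-space k-means; defaults to the number of
#'   conditions when `NULL`.
#' @param top_n_genes genes reported in the weight ranking.
#' @param seed master seed.
#' @param outdir output directory; `NULL` disables artifact writing.
#' @return A `cello_run_config` list.
#' @export
run_config <- function(input = NULL, format = "auto",
                       label_key = "condition",
                       preprocess = preprocess_config(),
                       k = 15, n_pcs = 50, h = 32,
                       budget_per_condition = 0.03, val_fraction = 0.2,
                       max_epochs = 200, patience = 30,
                       learning_rate = 0.01, weight_decay = 5e-4,
                       threshold = 0.5, k_clusters = NULL,
                       top_n_genes = 25, seed = 1, outdir = NULL) {
  structure(list(input = input, format = format, label_key = label_key,
                 preprocess = preprocess, k = k, n_pcs = n_pcs, h = h,
                 budget_per_condition = budget_per_condition,
                 val_fraction = val_fraction, max_epochs = max_epochs,
                 patience = patience, learning_rate = learning_rate,
                 weight_decay = weight_decay, threshold = threshold,
                 k_clusters = k_clusters, top_n_genes = top_n_genes,
                 seed = as.integer(seed), outdir = outdir),
            class = "cello_run_config")
}

#' Demo configurations mirroring the published protocols
#'
#' `"two_condition"` labels 40 cells per condition (the two-condition
#' organoid protocol); `"six_condition"` labels 30 per condition (the
#' six-timepoint drug-holiday protocol). Both keep the default 200-epoch /
#' patience-30 schedule, threshold 0.5 and top-25 gene ranking.
#'
#' @param which `"two_condition"` or `"six_condition"`.
#' @param ... overrides passed to [run_config()].
#' @return A `cello_run_config`.
#' @export
demo_config <- function(which = c("two_condition", "six_condition"), ...) {
  which <- match.arg(which)
  budget <- switch(which, two_condition = 40, six_condition = 30)
  run_config(budget_per_condition = budget, ...)
}

#' Run the full pipeline
#'
#' preprocess -> PCA -> kNN graph -> adjacency normalization -> masked GCN
#' training -> interpretation (probabilities, assignment, gene ranking,
#' latent k-means, composition) -> evaluation (Brier score, NMI of latent
#' vs PCA k-means against ground truth). When `config$outdir` is set, writes
#' `probabilities.csv`, `latent.csv`, `clusters.csv`, `gene_ranking.tsv`,
#' `composition.csv`, `report.json` and a `manifest.json` echoing the config
#' and per-stage timings.
#'
#' @param config a [run_config()].
#' @param expr optional `cello_expr`, bypassing `config$input`.
#' @return A `cello_result` list: `probabilities`, `latent`, `assigned`,
#'   `clusters`, `gene_ranking`, `composition`, `model`, `masks`, `graph`,
#'   `report`, `labels`, `cell_ids`.
#' @export
run_pipeline <- function(config, expr = NULL) {
  stopifnot(inherits(config, "cello_run_config"))
  timings <- list(); tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, f) {
    t0 <- tic()
    out <- tryCatch(f(), error = function(e)
      stop_param("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    timings[[name]] <<- round(tic() - t0, 3)
    out
  }

  if (is.null(expr)) {
    if (is.null(config$input)) stop_param("no input: set config$input or ",
                                          "pass `expr`")
    expr <- stage("load", function()
      load_dataset(config$input, config$format, config$label_key))
  }
  if (!is.null(config$preprocess) && expr$is_counts)
    expr <- stage("preprocess", function()
      standard_preprocess(expr, config$preprocess))

  pcs <- stage("pca", function()
    reduce_pca(expr, n_pcs = min(config$n_pcs, min(dim(expr$values)) - 1)))
  graph <- stage("knn", function() build_knn_graph(pcs, k = config$k))

  masks <- stage("masks", function()
    sample_masks(expr$labels, config$budget_per_condition,
                 config$val_fraction, seed = derive_seed(config$seed,
                                                         "masks")))
  tc <- train_config(max_epochs = config$max_epochs,
                     patience = config$patience,
                     learning_rate = config$learning_rate,
                     weight_decay = config$weight_decay, h = config$h,
                     seed = derive_seed(config$seed, "train"))
  model <- stage("train", function()
    train_gcn(as.matrix(expr$values), graph$A_norm, expr$labels, masks, tc))

  fw <- gcn_forward(model, graph$A_norm, as.matrix(expr$values))
  k_clusters <- if (is.null(config$k_clusters)) nlevels(expr$labels) else
    config$k_clusters
  assigned <- assign_condition(fw$P, config$threshold)
  clusters <- stage("cluster", function()
    cluster_latent(fw$H0, k = k_clusters,
                   seed = derive_seed(config$seed, "cluster")))
  ranking <- rank_genes(model, top_n = config$top_n_genes)
  comp <- composition_table(assigned, clusters)

  y <- as.integer(expr$labels)
  pred <- max.col(fw$P, ties.method = "first")
  report <- list(
    brier_all_cells = brier_score(expr$labels, fw$P),
    test_accuracy = mean(pred[masks$test_idx] == y[masks$test_idx]),
    val_accuracy = mean(pred[masks$val_idx] == y[masks$val_idx]),
    fraction_assigned = mean(assigned != "unassigned"),
    best_epoch = model$best_epoch,
    epochs_run = nrow(model$history),
    n_cells = nrow(fw$P), n_genes = ncol(expr$values),
    classes = model$classes)

  result <- structure(list(probabilities = fw$P, latent = fw$H0,
                           assigned = assigned, clusters = clusters,
                           gene_ranking = ranking, composition = comp,
                           model = model, masks = masks, graph = graph,
                           report = report, labels = expr$labels,
                           cell_ids = expr$cell_ids),
                      class = "cello_result")

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write_result(result, config$outdir)
    manifest <- list(config = config[setdiff(names(config), "preprocess")],
                     preprocess = config$preprocess,
                     timings = timings,
                     r_version = as.character(getRversion()),
                     package_version =
                       as.character(utils::packageVersion("cellograph")))
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  result
}

# CSV/TSV artifacts, keyed by cell id / gene name, deterministic byte-wise
# for a fixed result.
write_result <- function(result, outdir) {
  p <- as.data.frame(result$probabilities)
  p <- cbind(cell_id = result$cell_ids, p)
  write.csv(p, file.path(outdir, "probabilities.csv"), row.names = FALSE,
            quote = FALSE)
  l <- as.data.frame(result$latent)
  colnames(l) <- sprintf("latent%02d", seq_len(ncol(l)))
  write.csv(cbind(cell_id = result$cell_ids, l),
            file.path(outdir, "latent.csv"), row.names = FALSE, quote = FALSE)
  write.csv(data.frame(cell_id = result$cell_ids,
                       cluster = result$clusters,
                       assigned = as.character(result$assigned),
                       label = as.character(result$labels)),
            file.path(outdir, "clusters.csv"), row.names = FALSE,
            quote = FALSE)
  utils::write.table(result$gene_ranking,
                     file.path(outdir, "gene_ranking.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write.csv(data.frame(cluster = rownames(result$composition),
                       result$composition, check.names = FALSE),
            file.path(outdir, "composition.csv"), row.names = FALSE,
            quote = FALSE)
  jsonlite::write_json(result$report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Expand a parameter grid into run configurations
#'
#' Cartesian product of the supplied parameter vectors over a base config;
#' one `cello_run_config` per combination, with `outdir` suffixed by the
#' combination when set (supports sensitivity sweeps).
#'
#' @param base a [run_config()].
#' @param ... named vectors of parameter values, e.g. `h = c(16, 32)`,
#'   `k = c(10, 15)`.
#' @return List of `cello_run_config` objects.
#' @export
config_grid <- function(base, ...) {
  grid <- expand.grid(..., stringsAsFactors = FALSE)
  if (nrow(grid) == 0) return(list(base))
  lapply(seq_len(nrow(grid)), function(i) {
    cfg <- base
    for (nm in names(grid)) cfg[[nm]] <- grid[[nm]][i]
    if (!is.null(cfg$outdir))
      cfg$outdir <- file.path(cfg$outdir,
                              paste(names(grid), unlist(grid[i, ]),
                                    sep = "-", collapse = "_"))
    cfg
  })
}

#' @export
print.cello_result <- function(x, ...) {
  cat("cello_result:", x$report$n_cells, "cells,", x$report$n_genes,
      "genes,", length(x$report$classes), "conditions\n")
  cat(sprintf("  test accuracy %.3f | Brier (all cells) %.3f | assigned %.1f%%\n",
              x$report$test_accuracy, x$report$brier_all_cells,
              100 * x$report$fraction_assigned))
  cat(sprintf("  best epoch %d of %d run\n", x$report$best_epoch,
              x$report$epochs_run))
  invisible(x)
}
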