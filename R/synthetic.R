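#' Specify a synthetic multi-condition scRNA-seq dataset
#'
#' Parameterizes the negative-binomial count simulator used to exercise the
#' whole pipeline without external downloads. Each condition gets a disjoint
#' block of marker genes whose means are shifted up by `2^log_fold_effect` in
#' that condition's cells; an optional fraction of "mixed" cells per condition
#' is drawn from the arithmetic mean of two conditions' mean vectors while
#' keeping the label of their condition of origin — these emulate the
#' intermediate, ambiguous populations that per-cell condition probabilities
#' are designed to expose.
#'
#' @param n_conditions number of experimental conditions (>= 2).
#' @param cells_per_condition cells simulated per condition.
#' @param n_genes total genes.
#' @param n_markers_per_condition planted marker genes per condition;
#'   `n_markers_per_condition * n_conditions` must not exceed `n_genes`.
#' @param log_fold_effect non-negative log2 shift applied to a condition's
#'   marker-gene means in its own (non-mixed) cells.
#' @param mixed_fraction fraction in [0, 1) of each condition's cells drawn
#'   from an interpolated intermediate profile.
#' @param dispersion negative-binomial size (inverse-dispersion) parameter.
#' @param base_mean location of the log-normal distribution of per-gene
#'   baseline means.
#' @param seed integer seed; the generated dataset is a pure function of the
#'   spec including this seed.
#' @return A `cello_synth_spec` list.
#' @export
synthetic_spec <- function(n_conditions = 3, cells_per_condition = 300,
                           n_genes = 500, n_markers_per_condition = 20,
                           log_fold_effect = 2, mixed_fraction = 0,
                           dispersion = 2, base_mean = 2, seed = 1) {
  check_scalar(n_conditions, "n_conditions", lower = 2, integerish = TRUE)
  check_scalar(cells_per_condition, "cells_per_condition", lower = 1,
               integerish = TRUE)
  check_scalar(n_genes, "n_genes", lower = 1, integerish = TRUE)
  check_scalar(n_markers_per_condition, "n_markers_per_condition", lower = 0,
               integerish = TRUE)
  check_scalar(log_fold_effect, "log_fold_effect", lower = 0)
  check_scalar(mixed_fraction, "mixed_fraction", lower = 0, upper = 1 - 1e-12)
  check_scalar(dispersion, "dispersion", lower = 1e-12)
  check_scalar(base_mean, "base_mean", lower = 1e-12)
  check_scalar(seed, "seed", integerish = TRUE)
  if (n_markers_per_condition * n_conditions > n_genes)
    stop_param("marker overflow: ", n_markers_per_condition, " markers x ",
               n_conditions, " conditions > ", n_genes, " genes")
  structure(list(n_conditions = as.integer(n_conditions),
                 cells_per_condition = as.integer(cells_per_condition),
                 n_genes = as.integer(n_genes),
                 n_markers_per_condition = as.integer(n_markers_per_condition),
                 log_fold_effect = log_fold_effect,
                 mixed_fraction = mixed_fraction,
                 dispersion = dispersion,
                 base_mean = base_mean,
                 seed = as.integer(seed)),
            class = "cello_synth_spec")
}

#' Generate a synthetic multi-condition count dataset
#'
#' Draws counts from a negative binomial with log-normal per-gene baseline
#' means (so highly-variable-gene selection has structure to find). For
#' condition `c`, its planted marker genes' means are multiplied by
#' `2^log_fold_effect` in that condition's non-mixed cells. Mixed cells use
#' the arithmetic mean of their condition's mean vector and the next
#' condition's (cyclically), but keep their condition-of-origin label: their
#' label is wrong on purpose, emulating intermediate populations.
#'
#' @param spec a [synthetic_spec()].
#' @return A `cello_synth` list: `counts` (cells x genes integer matrix),
#'   `labels` (factor `cond1`, `cond2`, ...), `marker_truth` (per-condition
#'   list of marker gene column indices, disjoint), `mixed_flag` (per-cell
#'   logical), `gene_names`, `cell_ids`, and the `spec` echo.
#' @examples
#' d <- generate_multicondition_dataset(synthetic_spec(
#'   n_conditions = 2, cells_per_condition = 50, n_genes = 100,
#'   n_markers_per_condition = 10, seed = 7))
#' table(d$labels)
#' @export
generate_multicondition_dataset <- function(spec) {
  if (!inherits(spec, "cello_synth_spec"))
    stop_param("`spec` must come from synthetic_spec()")
  nc <- spec$n_conditions
  ncell <- spec$cells_per_condition
  ng <- spec$n_genes
  nm <- spec$n_markers_per_condition

  withr::with_seed(spec$seed, {
    base_mu <- rlnorm(ng, meanlog = log(spec$base_mean), sdlog = 1)
    marker_truth <- lapply(seq_len(nc), function(c)
      seq.int((c - 1L) * nm + 1L, length.out = nm))
    # per-condition mean vectors: baseline with that condition's markers lifted
    mu_cond <- matrix(rep(base_mu, nc), nrow = nc, byrow = TRUE)
    for (c in seq_len(nc))
      mu_cond[c, marker_truth[[c]]] <- base_mu[marker_truth[[c]]] *
        2^spec$log_fold_effect

    n_mixed <- floor(spec$mixed_fraction * ncell)
    counts <- matrix(0L, nrow = nc * ncell, ncol = ng)
    labels <- integer(nc * ncell)
    mixed_flag <- logical(nc * ncell)
    for (c in seq_len(nc)) {
      rows <- seq.int((c - 1L) * ncell + 1L, length.out = ncell)
      partner <- if (c == nc) 1L else c + 1L
      mu_mix <- (mu_cond[c, ] + mu_cond[partner, ]) / 2
      is_mixed <- seq_len(ncell) <= n_mixed
      for (i in seq_len(ncell)) {
        mu <- if (is_mixed[i]) mu_mix else mu_cond[c, ]
        counts[rows[i], ] <- rnbinom(ng, size = spec$dispersion, mu = mu)
      }
      labels[rows] <- c
      mixed_flag[rows] <- is_mixed
    }
    gene_names <- sprintf("gene%04d", seq_len(ng))
    cell_ids <- sprintf("cell%05d", seq_len(nc * ncell))
    dimnames(counts) <- list(cell_ids, gene_names)
    structure(list(counts = counts,
                   labels = factor(sprintf("cond%d", labels),
                                   levels = sprintf("cond%d", seq_len(nc))),
                   marker_truth = marker_truth,
                   mixed_flag = mixed_flag,
                   gene_names = gene_names,
                   cell_ids = cell_ids,
                   spec = spec),
              class = "cello_synth")
  })
}

#' Convert a synthetic dataset to an expression-matrix container
#'
#' @param dataset a `cello_synth` from [generate_multicondition_dataset()].
#' @return A `cello_expr` flagged as raw counts.
#' @export
as_expression_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "cello_synth"))
  expression_matrix(dataset$counts, dataset$gene_names, dataset$cell_ids,
                    dataset$labels, is_counts = TRUE)
}
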