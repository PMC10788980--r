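#' Preprocessing configuration
#'
#' Defaults follow common single-cell practice: cells with fewer than 300
#' expressed genes removed, genes expressed in fewer than 10 cells removed,
#' cells above 20% mitochondrial fraction removed, library-size normalization
#' to 10,000 reads per cell, log1p, then a mean/dispersion
#' highly-variable-gene filter (minimum mean 0.0125, maximum mean 3, minimum
#' normalized dispersion 0.5). The HVG thresholds assume genome-scale gene
#' counts; set `hvg = FALSE` for small panels where every gene's normalized
#' mean exceeds `hvg_max_mean` (e.g. the synthetic demos).
#'
#' @param min_genes minimum expressed genes per retained cell.
#' @param min_cells minimum expressing cells per retained gene.
#' @param max_mito_fraction mitochondrial-read fraction above which a cell is
#'   dropped; mitochondrial genes are identified by `mito_pattern`.
#' @param mito_pattern regular expression matched against gene names
#'   (case-insensitive) to find mitochondrial genes.
#' @param target_sum per-cell total after library-size normalization.
#' @param hvg logical, apply the highly-variable-gene filter.
#' @param hvg_min_mean,hvg_max_mean,hvg_min_dispersion HVG thresholds on the
#'   back-transformed (expm1) normalized scale, dispersion z-scored within 20
#'   mean bins.
#' @param n_top_genes optional integer: keep at most this many genes ranked by
#'   normalized dispersion (applied after the threshold filter), as in
#'   "top 2000 highly variable genes" workflows. `NULL` disables the cap.
#' @param scale_features z-score each gene to zero mean / unit variance after
#'   log1p (and HVG selection), clipping at `scale_max`; stabilizes both PCA
#'   and the gradient-based training downstream.
#' @param scale_max clip value for scaled features.
#' @return A `cello_prep_config` list.
#' @export
preprocess_config <- function(min_genes = 300, min_cells = 10,
                              max_mito_fraction = 0.2,
                              mito_pattern = "^MT-", target_sum = 1e4,
                              hvg = TRUE, hvg_min_mean = 0.0125,
                              hvg_max_mean = 3, hvg_min_dispersion = 0.5,
                              n_top_genes = NULL, scale_features = TRUE,
                              scale_max = 10) {
  check_scalar(min_genes, "min_genes", lower = 0, integerish = TRUE)
  check_scalar(min_cells, "min_cells", lower = 0, integerish = TRUE)
  check_scalar(max_mito_fraction, "max_mito_fraction", lower = 0, upper = 1)
  check_scalar(target_sum, "target_sum", lower = 1e-12)
  if (!is.null(n_top_genes))
    check_scalar(n_top_genes, "n_top_genes", lower = 1, integerish = TRUE)
  structure(list(min_genes = min_genes, min_cells = min_cells,
                 max_mito_fraction = max_mito_fraction,
                 mito_pattern = mito_pattern, target_sum = target_sum,
                 hvg = isTRUE(hvg), hvg_min_mean = hvg_min_mean,
                 hvg_max_mean = hvg_max_mean,
                 hvg_min_dispersion = hvg_min_dispersion,
                 n_top_genes = n_top_genes,
                 scale_features = isTRUE(scale_features),
                 scale_max = scale_max),
            class = "cello_prep_config")
}

# Normalized dispersion in the style of the classical mean/dispersion HVG
# selection: per-gene mean and variance/mean ratio of the expm1-transformed
# normalized values, dispersion z-scored within 20 equal-frequency mean bins.
hvg_statistics <- function(lognorm) {
  x <- expm1(lognorm)
  mu <- colMeans(x)
  v <- apply(x, 2, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(rank(mu, ties.method = "first"), breaks = 20, labels = FALSE)
  disp_norm <- disp
  for (b in unique(bins)) {
    idx <- bins == b
    m <- mean(disp[idx]); s <- sd(disp[idx])
    disp_norm[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - m) / s
  }
  list(mean = mu, dispersion_norm = disp_norm)
}

#' Standard single-cell preprocessing
#'
#' Applies, in this fixed order: cell filter (min expressed genes), gene
#' filter (min expressing cells), mitochondrial-fraction filter, library-size
#' normalization to `target_sum`, log1p, optionally a highly-variable-gene
#' filter, and optionally clipped per-gene z-scoring.
#'
#' @param expr a `cello_expr` flagged as raw counts.
#' @param config a [preprocess_config()].
#' @return A `cello_expr` with `is_counts = FALSE`, filtered and normalized.
#' @export
standard_preprocess <- function(expr, config = preprocess_config()) {
  stopifnot(inherits(expr, "cello_expr"))
  if (!expr$is_counts)
    stop_param("standard_preprocess() expects a matrix flagged as raw counts")
  x <- as.matrix(expr$values)

  keep_cells <- rowSums(x > 0) >= config$min_genes
  if (!any(keep_cells)) stop_param("all cells filtered: no cell expresses >= ",
                                   config$min_genes, " genes")
  x <- x[keep_cells, , drop = FALSE]

  keep_genes <- colSums(x > 0) >= config$min_cells
  if (!any(keep_genes)) stop_param("all genes filtered: no gene expressed in >= ",
                                   config$min_cells, " cells")
  x <- x[, keep_genes, drop = FALSE]
  genes <- expr$gene_names[keep_genes]

  mito <- grepl(config$mito_pattern, genes, ignore.case = TRUE)
  if (any(mito)) {
    frac <- rowSums(x[, mito, drop = FALSE]) / pmax(rowSums(x), 1)
    ok <- frac < config$max_mito_fraction
    if (!any(ok)) stop_param("all cells filtered by mitochondrial fraction")
    x <- x[ok, , drop = FALSE]
    keep_cells[keep_cells] <- ok
  }

  totals <- rowSums(x)
  if (any(totals == 0)) stop_param("cell with zero total counts survived ",
                                   "filtering; raise min_genes")
  x <- x * (config$target_sum / totals)
  x <- log1p(x)

  if (config$hvg) {
    st <- hvg_statistics(x)
    pass <- st$mean > config$hvg_min_mean & st$mean < config$hvg_max_mean &
      st$dispersion_norm > config$hvg_min_dispersion
    if (!any(pass))
      stop_param("all genes filtered by HVG thresholds; for small gene ",
                 "panels set hvg = FALSE")
    if (!is.null(config$n_top_genes) && sum(pass) > config$n_top_genes) {
      ord <- order(st$dispersion_norm, decreasing = TRUE)
      top <- ord[ord %in% which(pass)][seq_len(config$n_top_genes)]
      pass <- seq_along(genes) %in% top
    }
    x <- x[, pass, drop = FALSE]
    genes <- genes[pass]
  }

  if (config$scale_features) {
    x <- scale(x)
    x[is.na(x)] <- 0                      # constant genes
    x <- pmin(pmax(x, -config$scale_max), config$scale_max)
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
  }

  expression_matrix(x, genes, expr$cell_ids[keep_cells],
                    expr$labels[keep_cells], is_counts = FALSE)
}

#' Principal-component reduction
#'
#' Centers the expression matrix and returns the leading principal-component
#' scores, ordered by decreasing explained variance.
#'
#' @param expr a `cello_expr` (or plain numeric matrix).
#' @param n_pcs number of components; must be strictly less than
#'   `min(cells, genes)`.
#' @return cells x `n_pcs` score matrix with an `"explained_variance"`
#'   attribute (component variances, non-increasing).
#' @export
reduce_pca <- function(expr, n_pcs = 50) {
  x <- if (inherits(expr, "cello_expr")) as.matrix(expr$values) else
    as.matrix(expr)
  check_scalar(n_pcs, "n_pcs", lower = 1, integerish = TRUE)
  if (n_pcs >= min(dim(x)))
    stop_param("n_pcs (", n_pcs, ") must be < min(cells, genes) = ",
               min(dim(x)))
  p <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  scores <- p$x[, seq_len(n_pcs), drop = FALSE]
  attr(scores, "explained_variance") <- p$sdev[seq_len(n_pcs)]^2
  scores
}
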