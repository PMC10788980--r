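#' Threshold-based condition assignment
#'
#' A cell is assigned the class whose predicted probability reaches
#' `threshold`; if no class does, the cell is `"unassigned"`. For thresholds
#' above 0.5 at most one class can qualify; at exactly 0.5 a two-way tie is
#' possible and is broken toward the lower class index, with the affected
#' cells flagged in the `"tie"` attribute.
#'
#' @param P cells x c row-stochastic probability matrix (columns named by
#'   class, e.g. from [gcn_forward()]).
#' @param threshold assignment cutoff in (0, 1].
#' @return Factor of length cells with levels `c(classes, "unassigned")` and
#'   a logical `"tie"` attribute.
#' @export
assign_condition <- function(P, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1)
    stop_param("threshold must be in (0, 1], got ", threshold)
  P <- as.matrix(P)
  classes <- colnames(P)
  if (is.null(classes)) classes <- paste0("class", seq_len(ncol(P)))
  qual <- P >= threshold
  n_qual <- rowSums(qual)
  pick <- apply(qual, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  out <- factor(ifelse(is.na(pick), "unassigned", classes[pick]),
                levels = c(classes, "unassigned"))
  attr(out, "tie") <- n_qual > 1
  out
}

#' Rank genes by aggregated first-layer weights
#'
#' Each row of the first-layer weight matrix holds one gene's `h` latent
#' weights; summing per row and ordering from highest to lowest surfaces the
#' genes the model found most useful in separating the conditions. Signed
#' sums (the default) can cancel across latent dimensions, so an
#' absolute-value variant is offered.
#'
#' @param model a `cello_model`, or a genes x h weight matrix.
#' @param gene_names gene names matching the weight rows; taken from the
#'   matrix rownames when omitted.
#' @param top_n number of genes returned (default 25).
#' @param method `"signed"` row sums or `"absolute"` row sums of
#'   absolute values.
#' @return data.frame with columns `gene`, `score`, sorted by decreasing
#'   score, ties broken lexicographically by gene name.
#' @export
rank_genes <- function(model, gene_names = NULL, top_n = 25,
                       method = c("signed", "absolute")) {
  method <- match.arg(method)
  W0 <- if (inherits(model, "cello_model")) model$W0 else as.matrix(model)
  if (is.null(gene_names)) gene_names <- rownames(W0)
  if (is.null(gene_names))
    stop_param("gene_names required when the weight matrix has no rownames")
  if (length(gene_names) != nrow(W0))
    stop_param("gene_names length != number of weight rows")
  check_scalar(top_n, "top_n", lower = 1, integerish = TRUE)
  if (top_n > nrow(W0)) {
    warning("top_n (", top_n, ") exceeds number of genes (", nrow(W0),
            "); truncating", call. = FALSE)
    top_n <- nrow(W0)
  }
  score <- if (method == "signed") rowSums(W0) else rowSums(abs(W0))
  ord <- order(-score, gene_names)
  data.frame(gene = gene_names[ord[seq_len(top_n)]],
             score = score[ord[seq_len(top_n)]],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' k-means clustering of the latent embedding
#'
#' Clusters cells in the learned latent space, where proximity reflects both
#' transcriptomic similarity and condition-prototypicality, so the clusters
#' separate prototypical from intermediate populations. Runs `restarts`
#' seeded initializations and keeps the lowest-inertia solution.
#'
#' @param latent cells x h latent matrix (`H0` from [gcn_forward()]).
#' @param k number of clusters, `1 <= k <= cells`.
#' @param seed integer seed.
#' @param restarts random initializations.
#' @return Integer vector of cluster indices in `1..k`.
#' @export
cluster_latent <- function(latent, k, seed = 1, restarts = 10) {
  latent <- as.matrix(latent)
  check_scalar(k, "k", lower = 1, integerish = TRUE)
  if (k > nrow(latent))
    stop_param("k (", k, ") must be <= number of cells (", nrow(latent), ")")
  if (k == 1) return(rep(1L, nrow(latent)))
  withr::with_seed(seed,
    kmeans(latent, centers = k, nstart = restarts, iter.max = 100)$cluster)
}

#' Cluster x category composition table
#'
#' Fraction of each cluster's cells falling in each category (predicted
#' condition, ground-truth label, or cell type); rows sum to 1. Clusters
#' present in `levels(clusters)` but empty yield a zero row and a warning.
#'
#' @param categories per-cell category vector.
#' @param clusters per-cell cluster vector of the same length.
#' @return Matrix with one row per cluster and one column per category.
#' @export
composition_table <- function(categories, clusters) {
  if (length(categories) != length(clusters))
    stop_param("categories and clusters must have equal length")
  tab <- table(cluster = clusters, category = categories)
  counts <- matrix(as.numeric(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  rs <- rowSums(counts)
  empty <- rs == 0
  if (any(empty))
    warning("empty cluster(s): ", paste(rownames(counts)[empty],
                                        collapse = ", "), call. = FALSE)
  out <- counts / ifelse(rs == 0, 1, rs)
  out
}

#' Composition bar plot
#'
#' Simple stacked-bar visualization of a [composition_table()].
#'
#' @param comp cluster x category fraction matrix.
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot_composition <- function(comp, ...) {
  graphics::barplot(t(comp), legend.text = colnames(comp),
                    xlab = "cluster", ylab = "fraction", ...)
}
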