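#' Multiclass Brier score
#'
#' Mean over cells of the summed squared differences between the predicted
#' class probabilities and the one-hot truth:
#' `(1/N) * sum_i sum_j (p_ij - delta_ij)^2` with `delta_ij = 1` iff cell i's
#' true class is j. Lower is better; the range is [0, 2].
#'
#' @param true_labels per-cell true class (factor, or integer codes `1..C`
#'   matching the probability columns).
#' @param P N x C row-stochastic probability matrix.
#' @return Scalar in [0, 2].
#' @export
brier_score <- function(true_labels, P) {
  P <- as.matrix(P)
  y <- if (is.factor(true_labels)) as.integer(true_labels)
       else as.integer(true_labels)
  if (length(y) != nrow(P))
    stop_param("labels length (", length(y), ") != rows of P (", nrow(P), ")")
  if (any(y < 1 | y > ncol(P)))
    stop_param("label codes outside 1..", ncol(P))
  D <- matrix(0, nrow(P), ncol(P))
  D[cbind(seq_len(nrow(P)), y)] <- 1
  mean(rowSums((P - D)^2))
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized mutual information between two partitions
#'
#' Mutual information of the contingency table divided by the arithmetic
#' mean of the two partition entropies. Returns 0 when either partition has
#' a single class (zero entropy). Symmetric and invariant to relabeling.
#'
#' @param partition_a,partition_b equal-length label vectors.
#' @return Scalar in [0, 1].
#' @export
nmi <- function(partition_a, partition_b) {
  if (length(partition_a) != length(partition_b))
    stop_param("partitions must have equal length")
  n <- length(partition_a)
  tab <- table(partition_a, partition_b)
  pij <- tab / n
  pa <- rowSums(pij); pb <- colSums(pij)
  ha <- entropy_nats(pa); hb <- entropy_nats(pb)
  if (ha == 0 || hb == 0) return(0)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pa, pb)[nz]))
  max(0, min(1, mi / ((ha + hb) / 2)))
}

#' Benchmark clustering routes against ground-truth conditions
#'
#' Runs k-means on each supplied embedding (typically the PCA space and the
#' GCN latent space) `n_repeats` times with distinct seeds and scores every
#' run's partition against the ground-truth condition labels with [nmi()].
#' Additional methods can be plugged in as functions `f(seed)` returning a
#' per-cell partition; a failing adapter is recorded as missing and the
#' benchmark continues.
#'
#' @param embeddings named list of cells x d matrices.
#' @param labels ground-truth per-cell condition labels.
#' @param k clusters for the k-means routes.
#' @param n_repeats independent runs per method (default 100).
#' @param seed master seed; run r of method j uses a seed derived from it.
#' @param restarts k-means initializations per run (best inertia kept);
#'   10 is the conventional default and typically makes well-separated
#'   solutions identical across runs.
#' @param extra_methods optional named list of `function(seed)` adapters.
#' @return A `cello_benchmark` list: `nmi_by_method` (method -> numeric
#'   vector of NMI values, NA where an adapter failed), `summary`
#'   (data.frame of mean/sd per method), and a `config_echo`.
#' @export
benchmark_clustering <- function(embeddings, labels, k, n_repeats = 100,
                                 seed = 1, restarts = 10,
                                 extra_methods = NULL) {
  stopifnot(is.list(embeddings), length(names(embeddings)) ==
              length(embeddings))
  labels <- as_condition_factor(labels)
  check_scalar(n_repeats, "n_repeats", lower = 1, integerish = TRUE)
  methods_list <- lapply(embeddings, function(emb) {
    force(emb)
    function(run_seed) cluster_latent(emb, k = k, seed = run_seed,
                                      restarts = restarts)
  })
  names(methods_list) <- paste0("kmeans_", names(embeddings))
  methods_list <- c(methods_list, extra_methods)

  nmi_by_method <- lapply(names(methods_list), function(mn) {
    vapply(seq_len(n_repeats), function(r) {
      run_seed <- derive_seed(seed, paste0(mn, "_run", r))
      part <- tryCatch(methods_list[[mn]](run_seed),
                       error = function(e) NULL)
      if (is.null(part)) NA_real_ else nmi(part, labels)
    }, numeric(1))
  })
  names(nmi_by_method) <- names(methods_list)

  summ <- data.frame(
    method = names(nmi_by_method),
    mean_nmi = vapply(nmi_by_method, mean, numeric(1), na.rm = TRUE),
    sd_nmi = vapply(nmi_by_method, function(v)
      if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) else 0, numeric(1)),
    n_failed = vapply(nmi_by_method, function(v) sum(is.na(v)), numeric(1)),
    row.names = NULL)
  structure(list(nmi_by_method = nmi_by_method, summary = summ,
                 config_echo = list(k = k, n_repeats = n_repeats,
                                    seed = seed)),
            class = "cello_benchmark")
}

#' @export
print.cello_benchmark <- function(x, ...) {
  cat("Clustering benchmark (", x$config_echo$n_repeats, " repeats, k = ",
      x$config_echo$k, "):\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
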