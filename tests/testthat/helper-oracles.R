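# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use plain loops / dense arithmetic and share no code
# with the package internals.

# D^(-1/2) (A + I) D^(-1/2) by explicit dense arithmetic
dense_normalize_oracle <- function(A) {
  A <- as.matrix(A)
  n <- nrow(A)
  Ahat <- A + diag(n)
  d <- rowSums(Ahat)
  out <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      out[i, j] <- Ahat[i, j] / sqrt(d[i] * d[j])
  out
}

# one GCN layer via triple loop on dense matrices
dense_layer_oracle <- function(S, H, W, relu = TRUE) {
  S <- as.matrix(S); H <- as.matrix(H); W <- as.matrix(W)
  agg <- matrix(0, nrow(S), ncol(H))
  for (i in seq_len(nrow(S)))
    for (p in seq_len(ncol(H)))
      agg[i, p] <- sum(S[i, ] * H[, p])
  out <- matrix(0, nrow(S), ncol(W))
  for (i in seq_len(nrow(S)))
    for (q in seq_len(ncol(W)))
      out[i, q] <- sum(agg[i, ] * W[, q])
  if (relu) out[out < 0] <- 0
  out
}

# full two-layer forward pass composed from the layer oracle
dense_forward_oracle <- function(S, X, W0, W1) {
  H0 <- dense_layer_oracle(S, X, W0, relu = TRUE)
  Z1 <- dense_layer_oracle(S, H0, W1, relu = FALSE)
  P <- matrix(0, nrow(Z1), ncol(Z1))
  for (i in seq_len(nrow(Z1))) {
    e <- exp(Z1[i, ] - max(Z1[i, ]))
    P[i, ] <- e / sum(e)
  }
  list(H0 = H0, P = P)
}

# Brier score by explicit double loop
brier_loop_oracle <- function(y, P) {
  P <- as.matrix(P)
  tot <- 0
  for (i in seq_len(nrow(P)))
    for (j in seq_len(ncol(P)))
      tot <- tot + (P[i, j] - as.numeric(y[i] == j))^2
  tot / nrow(P)
}

# random symmetric zero-diagonal binary adjacency
random_adjacency <- function(n, p = 0.2, seed = 1) {
  withr::with_seed(seed, {
    A <- matrix(0, n, n)
    up <- which(upper.tri(A))
    A[up] <- rbinom(length(up), 1, p)
    A + t(A)
  })
}

# three well-separated Gaussian blobs, for clustering checks
blob_latent <- function(n_per = 30, d = 4, sep = 20, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(3 * d), 3, d) * sep
    x <- do.call(rbind, lapply(1:3, function(b)
      sweep(matrix(rnorm(n_per * d), n_per, d), 2, centers[b, ], "+")))
    list(x = x, truth = rep(1:3, each = n_per))
  })
}

# default synthetic demo: small enough for unit tests
small_synth <- function(seed = 1, ...) {
  generate_multicondition_dataset(synthetic_spec(
    n_conditions = 2, cells_per_condition = 60, n_genes = 120,
    n_markers_per_condition = 10, seed = seed, ...))
}

no_hvg <- function(...) preprocess_config(hvg = FALSE, min_genes = 10,
                                          min_cells = 1, ...)
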