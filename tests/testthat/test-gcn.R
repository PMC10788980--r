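test_that("gcn_layer reduces to the input on an isolated node", {
  S <- normalize_adjacency(matrix(0, 1, 1))
  h <- matrix(c(1.5, -2, 0.25), 1, 3)
  expect_equal(gcn_layer(S, h, diag(3), "identity"), h, ignore_attr = TRUE)
})

test_that("gcn_layer matches hand arithmetic on two nodes one edge", {
  S <- normalize_adjacency(rbind(c(0, 1), c(1, 0)))
  out <- gcn_layer(S, diag(2), diag(2), "identity")
  expect_equal(out, matrix(0.5, 2, 2), ignore_attr = TRUE)
})

test_that("gcn_layer and gcn_forward match dense loop oracles", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- sample(10:30, 1); m <- sample(5:20, 1); h <- sample(2:8, 1)
      A <- random_adjacency(n, p = 0.2, seed = seed + 50)
      X <- matrix(rnorm(n * m), n, m)
      W0 <- matrix(rnorm(m * h) / 3, m, h)
      W1 <- matrix(rnorm(h * 3) / 3, h, 3)
    })
    S <- normalize_adjacency(A)
    expect_lt(max(abs(gcn_layer(S, X, W0, "relu") -
                        dense_layer_oracle(S, X, W0))), 1e-6)
    model <- structure(list(W0 = W0, W1 = W1, h = h,
                            classes = paste0("c", 1:3),
                            activation = "relu"),
                       class = "cello_model")
    fw <- gcn_forward(model, S, X)
    oracle <- dense_forward_oracle(S, X, W0, W1)
    expect_lt(max(abs(fw$H0 - oracle$H0)), 1e-6)
    expect_lt(max(abs(fw$P - oracle$P)), 1e-6)
    expect_equal(rowSums(fw$P), rep(1, n), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("shape mismatches raise parameterization errors", {
  S <- normalize_adjacency(random_adjacency(5, seed = 1))
  expect_error(gcn_layer(S, matrix(0, 4, 2), diag(2)), "conform")
  expect_error(gcn_layer(S, matrix(0, 5, 2), matrix(0, 3, 2)), "columns")
})

test_that("softmax matches closed forms and is shift invariant", {
  expect_equal(as.vector(row_softmax(c(0, 0))), c(0.5, 0.5))
  expect_equal(as.vector(row_softmax(c(log(2), 0))), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  z <- matrix(rnorm(12), 3, 4)
  expect_lt(max(abs(row_softmax(z + 100) - row_softmax(z))), 1e-12)
  expect_equal(rowSums(row_softmax(z)), rep(1, 3), tolerance = 1e-12)
  expect_true(all(row_softmax(z) > 0))
  expect_lt(max(abs(rowSums(row_softmax(matrix(c(1000, -1000), 1))) - 1)),
            1e-12)
  expect_error(row_softmax(c(Inf, 0)), "finite")
})

test_that("zero second-layer weights give uniform probabilities", {
  S <- normalize_adjacency(random_adjacency(8, seed = 2))
  X <- matrix(rnorm(8 * 4), 8, 4)
  model <- init_model(4, 3, c("a", "b", "c"), seed = 1)
  model$W1[] <- 0
  fw <- gcn_forward(model, S, X)
  expect_equal(fw$P, matrix(1 / 3, 8, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("mask sampling honors published per-condition budgets", {
  lab2 <- rep(c("ctrl", "treated"), c(1242, 1242))
  m2 <- sample_masks(lab2, 40, seed = 1)
  expect_length(m2$train_idx, 80)
  lab6 <- rep(paste0("t", 1:6), each = 500)
  m6 <- sample_masks(lab6, 30, seed = 1)
  expect_length(m6$train_idx, 180)
  # every condition contributes exactly its budget
  expect_equal(as.vector(table(lab6[m6$train_idx])), rep(30, 6))
})

test_that("mask sets are disjoint, exhaustive and seeded", {
  lab <- rep(c("a", "b", "c"), each = 50)
  m <- sample_masks(lab, 0.03, val_fraction = 0.2, seed = 9)
  all_idx <- c(m$train_idx, m$val_idx, m$test_idx)
  expect_equal(sort(all_idx), 1:150)
  expect_equal(anyDuplicated(all_idx), 0)
  expect_equal(as.vector(table(lab[m$train_idx])), rep(2, 3))  # 3% of 50 -> 2
  expect_identical(sample_masks(lab, 0.03, seed = 9), m)
  expect_false(identical(sample_masks(lab, 0.03, seed = 10)$train_idx,
                         m$train_idx))
})

test_that("a budget exceeding a condition size names the condition", {
  lab <- rep(c("big", "tiny"), c(100, 5))
  expect_error(sample_masks(lab, 10, seed = 1), "tiny")
})

test_that("cross-entropy matches closed forms and honors the mask", {
  P <- rbind(c(1, 0), c(0.5, 0.5), c(0.9, 0.1))
  y <- c(1L, 1L, 2L)
  expect_equal(cross_entropy(rbind(c(1, 0)), 1L, 1L), 0)
  expect_equal(cross_entropy(P, y, 2L), log(2), tolerance = 1e-12)
  # perturbing probabilities outside the mask leaves the loss unchanged
  P2 <- P; P2[3, ] <- c(0.01, 0.99)
  expect_equal(cross_entropy(P, y, 1:2), cross_entropy(P2, y, 1:2))
  # zero probability is clipped to a large finite loss
  expect_true(is.finite(cross_entropy(rbind(c(0, 1)), 1L, 1L)))
  expect_error(cross_entropy(P, y, integer(0)), "nonempty")
})

test_that("training is reproducible and honors early stopping", {
  d <- small_synth(seed = 12)
  pr <- standard_preprocess(as_expression_matrix(d), no_hvg())
  pcs <- reduce_pca(pr, 10)
  g <- build_knn_graph(pcs, k = 8)
  mk <- sample_masks(pr$labels, 0.03, seed = 12)
  cfg <- train_config(max_epochs = 60, patience = 10, h = 8, seed = 12)
  X <- as.matrix(pr$values)
  m1 <- train_gcn(X, g$A_norm, pr$labels, mk, cfg)
  m2 <- train_gcn(X, g$A_norm, pr$labels, mk, cfg)
  expect_identical(m1$W0, m2$W0)
  expect_identical(m1$W1, m2$W1)
  # returned model achieves the minimum recorded validation loss
  expect_equal(m1$history$val_loss[m1$best_epoch],
               min(m1$history$val_loss))
  # stopping: either the epoch budget ran out or patience was exhausted
  expect_lte(nrow(m1$history), cfg$max_epochs)
  if (nrow(m1$history) < cfg$max_epochs)
    expect_equal(nrow(m1$history) - m1$best_epoch, cfg$patience)
})

test_that("training defaults follow the published protocol", {
  cfg <- train_config()
  expect_equal(cfg$max_epochs, 200L)
  expect_equal(cfg$patience, 30L)
  expect_error(train_config(max_epochs = 10, patience = 20), "patience")
})

test_that("the GCN learns a separable two-condition dataset", {
  d <- small_synth(seed = 13, log_fold_effect = 2)
  pr <- standard_preprocess(as_expression_matrix(d), no_hvg())
  pcs <- reduce_pca(pr, 10)
  g <- build_knn_graph(pcs, k = 8)
  mk <- sample_masks(pr$labels, 0.03, seed = 13)
  m <- train_gcn(as.matrix(pr$values), g$A_norm, pr$labels, mk,
                 train_config(h = 8, seed = 13))
  fw <- gcn_forward(m, g$A_norm, as.matrix(pr$values))
  acc <- mean(max.col(fw$P)[mk$test_idx] ==
                as.integer(pr$labels)[mk$test_idx])
  expect_gt(acc, 0.9)
})

test_that("checkpoints round-trip the trained weights", {
  model <- init_model(6, 4, c("x", "y"), seed = 3)
  rownames(model$W0) <- paste0("g", 1:6)
  path <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(model, path)
  back <- read_checkpoint(path)
  expect_equal(back$W0, model$W0)
  expect_equal(back$W1, model$W1, ignore_attr = TRUE)
  expect_equal(back$classes, model$classes)
})
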