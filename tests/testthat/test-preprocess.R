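test_that("normalization halves a cell with twice the target total", {
  # 2 cells x 4 genes; cell 1 totals 20000, cell 2 totals 10000
  x <- rbind(c(8000, 6000, 4000, 2000), c(4000, 3000, 2000, 1000))
  ex <- expression_matrix(x, paste0("g", 1:4), c("a", "b"), c("c1", "c2"))
  out <- standard_preprocess(ex, preprocess_config(
    min_genes = 1, min_cells = 1, hvg = FALSE, scale_features = FALSE))
  expect_equal(as.vector(out$values[1, ]), log1p(x[1, ] / 2),
               tolerance = 1e-12)
  expect_equal(as.vector(out$values[2, ]), log1p(x[2, ]), tolerance = 1e-12)
  expect_false(out$is_counts)
})

test_that("cells expressing too few genes are removed", {
  x <- matrix(1, 5, 4)
  x[3, ] <- 0                       # cell 3 expresses nothing
  ex <- expression_matrix(x, paste0("g", 1:4), paste0("c", 1:5),
                          rep(c("a", "b"), length.out = 5))
  out <- standard_preprocess(ex, preprocess_config(
    min_genes = 1, min_cells = 1, hvg = FALSE, scale_features = FALSE))
  expect_equal(nrow(out$values), 4)
  expect_false("c3" %in% out$cell_ids)
})

test_that("gene and mito filters apply in order and can empty the matrix", {
  x <- matrix(rpois(40, 5) + 1, 4, 10)
  genes <- c(paste0("g", 1:8), "MT-CO1", "MT-CO2")
  x[, 9:10] <- 50                   # heavy mitochondrial load
  ex <- expression_matrix(x, genes, paste0("c", 1:4), rep(c("a", "b"), 2))
  expect_error(standard_preprocess(ex, preprocess_config(
    min_genes = 1, min_cells = 1, max_mito_fraction = 0.05, hvg = FALSE)),
    "mitochondrial")
  expect_error(standard_preprocess(ex, preprocess_config(
    min_genes = 11, min_cells = 1, hvg = FALSE)), "all cells filtered")
  # a rarely expressed gene is dropped
  x2 <- matrix(5, 4, 3); x2[2:4, 3] <- 0
  ex2 <- expression_matrix(x2, paste0("g", 1:3), paste0("c", 1:4),
                           rep(c("a", "b"), 2))
  out <- standard_preprocess(ex2, preprocess_config(
    min_genes = 1, min_cells = 2, hvg = FALSE, scale_features = FALSE))
  expect_equal(out$gene_names, c("g1", "g2"))
})

test_that("preprocessing requires a counts-flagged matrix", {
  ex <- expression_matrix(matrix(0.5, 2, 2), c("g1", "g2"), c("a", "b"),
                          c("x", "y"), is_counts = FALSE)
  expect_error(standard_preprocess(ex), "raw counts")
})

test_that("HVG filter keeps high-dispersion genes and can error out", {
  d <- small_synth(seed = 3)
  ex <- as_expression_matrix(d)
  # thresholds scaled to the small panel: keep genes above-median mean
  out <- standard_preprocess(ex, preprocess_config(
    min_genes = 1, min_cells = 1, hvg = TRUE, hvg_min_mean = 0,
    hvg_max_mean = Inf, hvg_min_dispersion = 0, scale_features = FALSE))
  expect_lt(ncol(out$values), ncol(ex$values))
  expect_error(standard_preprocess(ex, preprocess_config(
    min_genes = 1, min_cells = 1, hvg = TRUE, hvg_min_mean = 1e9)),
    "HVG")
  # n_top_genes caps the panel
  out2 <- standard_preprocess(ex, preprocess_config(
    min_genes = 1, min_cells = 1, hvg = TRUE, hvg_min_mean = 0,
    hvg_max_mean = Inf, hvg_min_dispersion = -Inf, n_top_genes = 20,
    scale_features = FALSE))
  expect_equal(ncol(out2$values), 20)
})

test_that("scaled features have zero mean and bounded magnitude", {
  d <- small_synth(seed = 4)
  out <- standard_preprocess(as_expression_matrix(d), no_hvg())
  expect_equal(max(abs(colMeans(out$values))), 0, tolerance = 1e-10)
  expect_lte(max(abs(out$values)), 10)
})

test_that("PCA recovers exactly rank-2 data and orders variance", {
  withr::with_seed(2, {
    basis <- matrix(rnorm(2 * 20), 2, 20)
    scores <- matrix(rnorm(50 * 2), 50, 2) %*% diag(c(5, 1))
    x <- scores %*% basis
  })
  p <- reduce_pca(x, 2)
  center <- colMeans(x)
  recon <- p %*% t(prcomp(x, rank. = 2)$rotation)
  expect_lt(max(abs(sweep(x, 2, center) - recon)), 1e-8)
  ev <- attr(reduce_pca(x, 5), "explained_variance")
  expect_true(all(diff(ev) <= 1e-12))
  expect_error(reduce_pca(x, 20), "n_pcs")
})
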