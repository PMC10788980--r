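test_that("generated dataset has the requested shape and label counts", {
  d <- generate_multicondition_dataset(synthetic_spec(
    n_conditions = 3, cells_per_condition = 100, n_genes = 500, seed = 5))
  expect_equal(dim(d$counts), c(300, 500))
  expect_equal(as.vector(table(d$labels)), rep(100, 3))
  expect_true(all(d$counts >= 0))
  expect_true(all(d$counts == round(d$counts)))
  expect_length(d$marker_truth, 3)
  expect_equal(anyDuplicated(unlist(d$marker_truth)), 0)
})

test_that("same seed gives a bit-identical dataset, different seed does not", {
  s <- synthetic_spec(n_conditions = 2, cells_per_condition = 30,
                      n_genes = 80, seed = 42)
  d1 <- generate_multicondition_dataset(s)
  d2 <- generate_multicondition_dataset(s)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$labels, d2$labels)
  s2 <- synthetic_spec(n_conditions = 2, cells_per_condition = 30,
                       n_genes = 80, seed = 43)
  expect_false(identical(generate_multicondition_dataset(s2)$counts,
                         d1$counts))
})

test_that("marker genes are up in their own condition for a real effect", {
  d <- generate_multicondition_dataset(synthetic_spec(
    n_conditions = 3, cells_per_condition = 200, n_genes = 300,
    n_markers_per_condition = 15, log_fold_effect = 2, seed = 8))
  y <- as.integer(d$labels)
  for (c in 1:3) {
    own <- colMeans(d$counts[y == c, d$marker_truth[[c]], drop = FALSE])
    other <- colMeans(d$counts[y != c, d$marker_truth[[c]], drop = FALSE])
    expect_true(mean(own) > mean(other))
  }
})

test_that("marker planting is detectable by a rank test at alpha 0.01", {
  d <- generate_multicondition_dataset(synthetic_spec(
    n_conditions = 2, cells_per_condition = 200, n_genes = 200,
    n_markers_per_condition = 10, log_fold_effect = 1, seed = 9))
  y <- as.integer(d$labels)
  g <- d$marker_truth[[1]]
  own <- rowSums(d$counts[y == 1, g, drop = FALSE])
  other <- rowSums(d$counts[y == 2, g, drop = FALSE])
  expect_lt(wilcox.test(own, other, alternative = "greater")$p.value, 0.01)
})

test_that("non-marker genes show no systematic condition difference", {
  d <- generate_multicondition_dataset(synthetic_spec(
    n_conditions = 2, cells_per_condition = 500, n_genes = 100,
    n_markers_per_condition = 5, log_fold_effect = 2, seed = 10))
  y <- as.integer(d$labels)
  nonmark <- setdiff(seq_len(100), unlist(d$marker_truth))
  pvals <- vapply(withr::with_seed(77, sample(nonmark, 30)), function(g)
    t.test(d$counts[y == 1, g], d$counts[y == 2, g])$p.value, numeric(1))
  # under the null, p-values are uniform; a KS test should not reject
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("mixed cells keep the label of their condition of origin", {
  d <- generate_multicondition_dataset(synthetic_spec(
    n_conditions = 2, cells_per_condition = 100, n_genes = 100,
    mixed_fraction = 0.3, seed = 11))
  expect_equal(sum(d$mixed_flag), 60)   # 30 per condition
  expect_equal(as.vector(table(d$labels)), c(100, 100))
  # mixed cells of condition 1 sit between the two conditions on markers
  y <- as.integer(d$labels)
  m2 <- d$marker_truth[[2]]
  pure1 <- mean(d$counts[y == 1 & !d$mixed_flag, m2])
  mix1 <- mean(d$counts[y == 1 & d$mixed_flag, m2])
  pure2 <- mean(d$counts[y == 2 & !d$mixed_flag, m2])
  expect_true(pure1 < mix1 && mix1 < pure2)
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(n_conditions = 1), "n_conditions")
  expect_error(synthetic_spec(n_conditions = 4, n_genes = 30,
                              n_markers_per_condition = 10),
               "marker overflow")
  expect_error(synthetic_spec(mixed_fraction = 1), "mixed_fraction")
  expect_error(generate_multicondition_dataset(list()), "synthetic_spec")
})
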