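# Spearman correlation structure, feature ordering, and matrix similarity.

test_that("self- and monotone-transform correlations are exactly 1", {
  set.seed(6)
  x <- matrix(rnorm(40), 10, 4)
  colnames(x) <- paste0("f", 1:4)
  x[, 2] <- exp(x[, 1])          # strictly monotone transform of column 1
  rho <- spearman_matrix(x)
  expect_equal(unname(diag(rho)), rep(1, 4))
  expect_equal(unname(rho[1, 2]), 1)
  expect_true(isSymmetric(unclass(rho)))
  expect_true(all(abs(rho) <= 1 + 1e-12, na.rm = TRUE))
})

test_that("a hand-ranked pair matches the rank-formula oracle", {
  # (1,2,3,4) vs (1,3,2,4): one swapped adjacent pair of ranks
  x <- cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
  oracle <- cor(rank(x[, 1]), rank(x[, 2]))  # = 1 - 6*2/(4*15) = 0.8
  expect_equal(oracle, 0.8)
  expect_equal(unname(spearman_matrix(x)["a", "b"]), oracle)
  # ties handled by average ranks
  xt <- cbind(a = c(1, 1, 2, 3), b = c(2, 2, 3, 5))
  expect_equal(unname(spearman_matrix(xt)["a", "b"]),
               cor(rank(xt[, 1]), rank(xt[, 2])))
})

test_that("constant columns are flagged and too-few subjects rejected", {
  x <- cbind(a = 1:5, b = rep(2, 5))
  suppressWarnings(rho <- spearman_matrix(x))
  expect_identical(attr(rho, "constant"), "b")
  expect_true(is.na(rho["a", "b"]))
  expect_error(spearman_matrix(x[1:2, ]), "3 subjects")
})

test_that("reference ordering recovers block structure and is a permutation", {
  # two clean blocks: features 1-3 mutually correlated, 4-6 mutually
  # correlated, across-block correlation ~ 0
  set.seed(12)
  n <- 60
  u <- rnorm(n)
  v <- rnorm(n)
  x <- cbind(u + rnorm(n, sd = .1), u + rnorm(n, sd = .1),
             u + rnorm(n, sd = .1), v + rnorm(n, sd = .1),
             v + rnorm(n, sd = .1), v + rnorm(n, sd = .1))
  colnames(x) <- paste0("f", 1:6)
  rho <- spearman_matrix(x)
  ord <- reference_order(rho)
  expect_setequal(ord, 1:6)
  blocks <- (ord > 3) + 0
  # members of each block are contiguous in the leaf order
  expect_identical(sum(abs(diff(blocks))), 1)
  # deterministic under a fixed input
  expect_identical(reference_order(rho), ord)
})

test_that("matrix similarity has its algebraic fixed points", {
  set.seed(13)
  x <- matrix(rnorm(80), 20, 4)
  colnames(x) <- paste0("f", 1:4)
  m <- spearman_matrix(x)
  expect_equal(compare_matrices(m, m), 1)
  neg <- unclass(m)
  expect_equal(compare_matrices(m, -neg), -1)
  expect_error(compare_matrices(m, spearman_matrix(matrix(rnorm(60), 20, 3))),
               "same feature set")
})

test_that("independent noise tables have near-zero structural similarity", {
  set.seed(14)
  sims <- replicate(20, {
    a <- spearman_matrix(matrix(rnorm(10 * 21), 10, 21))
    b <- spearman_matrix(matrix(rnorm(10 * 21), 10, 21))
    compare_matrices(a, b)   # 210 upper-triangle pairs
  })
  expect_lt(abs(mean(sims)), 0.2)
  expect_lt(max(abs(sims)), 0.4)
})

test_that("mask style barely changes the consensus correlation structure", {
  exp <- cached_experiment(101L)
  expect_gt(exp$correlations$similarity_rect_irreg, 0.9)
  # the same feature order can re-render the other matrix losslessly
  ord <- exp$correlations$reference_order
  m <- exp$correlations$conseg_rectangular
  expect_identical(sort(colnames(m)[ord]), sort(colnames(m)))
})
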