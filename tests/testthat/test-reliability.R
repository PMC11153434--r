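# ICC(2,1), category scheme, designs and summaries.

test_that("perfect agreement gives ICC = 1", {
  m <- matrix(c(1, 1, 2, 2, 3, 3), 3, 2, byrow = TRUE)
  expect_equal(icc_a1(m)$icc, 1)
})

test_that("the hand-decomposed example gives 8/9", {
  # rows (1,2), (3,4), (5,6): SSR = 16, SSC = 1.5, SSE = 0 by hand, so
  # ICC = 8 / (8 + (2/3) * 1.5) = 8/9
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2, byrow = TRUE)
  r <- icc_a1(m)
  expect_equal(r$icc, 8 / 9)
  expect_equal(r$ms_rows, 8)
  expect_equal(r$ms_cols, 1.5)
  expect_equal(r$ms_error, 0)
})

test_that("icc_a1 agrees with an aov-based oracle on random matrices", {
  set.seed(11)
  for (rep in 1:150) {
    n <- sample(2:30, 1)
    k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k, sd = runif(1, 0.5, 3)), n, k)
    expect_equal(icc_a1(m)$icc, oracle_icc_a1(m), tolerance = 1e-10)
  }
})

test_that("icc_a1 is invariant to shifting and positive scaling", {
  set.seed(5)
  m <- matrix(rnorm(20), 5, 4)
  base <- icc_a1(m)$icc
  expect_equal(icc_a1(m + 100)$icc, base, tolerance = 1e-9)
  expect_equal(icc_a1(m * 7)$icc, base, tolerance = 1e-9)
})

test_that("degenerate matrices are flagged, not crashed", {
  m <- matrix(2, 4, 3)
  r <- icc_a1(m)
  expect_false(r$valid)
  expect_true(is.na(r$icc))
  expect_error(icc_a1(matrix(c(1, NA, 2, 3), 2, 2)), "finite")
  expect_error(icc_a1(matrix(1:3, 3, 1)), "2 subjects and 2 raters")
})

test_that("the category scheme reproduces the printed partition", {
  expect_identical(categorize_icc(0.95), "excellent")
  expect_identical(categorize_icc(0.9), "excellent")
  expect_identical(categorize_icc(0.8999), "good")
  expect_identical(categorize_icc(0.75), "good")
  expect_identical(categorize_icc(0.74), "moderate")
  expect_identical(categorize_icc(0.5), "moderate")
  expect_identical(categorize_icc(0.49), "poor")
  expect_identical(categorize_icc(0), "poor")
  # negatives are categorized by absolute value
  expect_identical(categorize_icc(-0.3), "poor")
  expect_identical(categorize_icc(-0.92), "excellent")
  r <- icc_a1(matrix(c(1, 9, 9.5, 1.2, 2, 8), 3, 2))
  if (r$icc < 0) expect_true(r$negative_flag)
})

# a small synthetic feature table: 2 features, 6 cases, all method/mask cells
fake_table <- function(noise = 0) {
  methods <- c("MASAC", "AP", "ST", "41MAX", "ConSeg")
  styles <- c("rectangular", "irregular")
  set.seed(2)
  base <- data.frame(case = 1:6, f1 = (1:6) * 2, f2 = sin(1:6) + 3)
  rows <- list()
  for (m in methods) for (s in styles) {
    r <- base
    r$method <- m
    r$mask_style <- s
    r$f1 <- r$f1 + rnorm(6, sd = noise)
    r$f2 <- r$f2 + rnorm(6, sd = noise)
    rows[[length(rows) + 1]] <- r
  }
  gt <- base
  gt$method <- "GT"
  gt$mask_style <- "none"
  rows[[length(rows) + 1]] <- gt
  tab <- do.call(rbind, rows)
  names(tab)[names(tab) == "f1"] <- "firstorder_Energy"
  names(tab)[names(tab) == "f2"] <- "firstorder_Mean"
  tab
}

test_that("identical raters give ICC 1 in every design", {
  tab <- fake_table(noise = 0)
  for (d in c("between_masks", "among_methods", "vs_ground_truth")) {
    res <- run_design(tab, design_spec(d))
    expect_true(all(res$icc == 1))
  }
})

test_that("between-masks design uses k = 2 over all 13 synthetic cases", {
  exp <- cached_experiment(101L)
  spec <- design_spec("between_masks")
  expect_identical(spec$k, 2L)
  m <- conseg:::measurement_matrix(
    exp$features, "firstorder_Energy",
    list(list(method = "ConSeg", mask_style = "rectangular"),
         list(method = "ConSeg", mask_style = "irregular")))
  expect_identical(dim(m), c(13L, 2L))
  expect_false(any(is.na(m)))
})

test_that("permuting subject order leaves every ICC unchanged", {
  tab <- fake_table(noise = 0.3)
  res1 <- run_design(tab, design_spec("between_masks"))
  set.seed(4)
  perm <- sample(unique(tab$case))
  tab2 <- tab
  tab2$case <- perm[tab$case]
  res2 <- run_design(tab2, design_spec("between_masks"))
  res2 <- res2[order(res2$group, res2$feature), ]
  res1 <- res1[order(res1$group, res1$feature), ]
  expect_equal(res1$icc, res2$icc, tolerance = 1e-12)
})

test_that("missing rater columns raise a named error", {
  tab <- fake_table()
  tab <- tab[tab$method != "AP", ]
  expect_error(run_design(tab, design_spec("among_methods")), "AP")
})

test_that("summaries conserve counts and report the stable set", {
  tab <- fake_table(noise = 0)
  res <- run_design(tab, design_spec("between_masks"))
  s <- summarize_icc(res, total_features = 107L)
  expect_true(all(rowSums(s$category_counts) == 2))  # 2 features per group
  expect_equal(unname(s$median_icc), rep(1, 5))
  expect_identical(sort(s$stable_features),
                   c("firstorder_Energy", "firstorder_Mean"))
  expect_identical(s$n_stable, 2L)
  expect_equal(s$pct_stable, 100 * 2 / 107)
  # category counts sum to the number of non-excluded, non-negative features
  noisy <- run_design(fake_table(noise = 2), design_spec("between_masks"))
  s2 <- summarize_icc(noisy)
  for (g in rownames(s2$category_counts)) {
    sub <- noisy[noisy$group == g & noisy$valid, ]
    expect_identical(sum(s2$category_counts[g, ]),
                     sum(!sub$negative_flag))
  }
})

test_that("adding noise to one rater degrades the median ICC monotonically", {
  set.seed(31)
  meds <- vapply(c(0, 0.5, 2), function(sigma) {
    med <- numeric(50)
    for (r in 1:50) {
      m <- matrix(rep(rnorm(10, sd = 3), 3), 10, 3)
      m[, 3] <- m[, 3] + rnorm(10, sd = sigma)
      med[r] <- icc_a1(m)$icc
    }
    median(med)
  }, 0)
  expect_true(all(diff(meds) <= 0))
})
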