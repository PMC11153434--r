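# The four individual segmentation methods.

test_that("41MAX reproduces the threshold arithmetic on a toy row", {
  img <- image_volume(array(c(10, 5, 4, 1), c(4, 1, 1)), c(1, 1, 1))
  init <- binary_mask(array(TRUE, c(4, 1, 1)), c(1, 1, 1))
  r <- segment_41max(img, init)  # threshold 4.1
  expect_identical(which(r$mask$data), c(1L, 2L))
  expect_equal(r$params_used$threshold, 4.1)
  expect_equal(r$params_used$fraction, 0.41)
})

test_that("41MAX returns the whole mask on uniform input", {
  img <- image_volume(array(2, c(4, 4, 2)), c(1, 1, 1))
  init <- binary_mask(array(TRUE, c(4, 4, 2)), c(1, 1, 1))
  r <- segment_41max(img, init)
  expect_identical(r$mask$data, init$data)
})

test_that("raising the 41MAX fraction never adds voxels", {
  cs <- small_case()
  prev <- NULL
  for (f in c(0.3, 0.41, 0.6, 0.8)) {
    r <- segment_41max(cs$image, cs$rect, fraction = f)
    if (!is.null(prev)) expect_true(all(prev$data[r$mask$data]))
    prev <- r$mask
  }
})

test_that("contrast-oriented thresholding limiting cases behave analytically", {
  img <- two_level_image()
  init <- binary_mask(array(TRUE, dim(img$data)), img$spacing)
  # a = 0, b = 1: threshold equals the background level, mask fills init
  r <- segment_st(img, init, st_params(a = 0, b = 1))
  expect_identical(r$mask$data, init$data)
  expect_equal(r$params_used$threshold, 1)
  # a = 1, b = 0 on a homogeneous tumor: contour is the max plateau
  r2 <- segment_st(img, init, st_params(a = 1, b = 0))
  expect_identical(r2$mask$data, two_level_mask(img)$data)
  expect_equal(r2$params_used$threshold, 8)
  # default weights: threshold = 0.5 * 8 + 0.5 * 1 = 4.5 by hand
  r3 <- segment_st(img, init, st_params())
  expect_equal(r3$params_used$threshold, 4.5)
  expect_identical(r3$mask$data, two_level_mask(img)$data)
})

test_that("affinity propagation recovers a two-level split", {
  # two well-separated levels, high level the larger group (36 vs 28)
  arr <- array(1, c(4, 4, 4))
  arr[1:3, , 1:3] <- 8
  img <- image_volume(arr, c(1, 1, 1))
  init <- binary_mask(array(TRUE, dim(arr)), c(1, 1, 1))
  # exhaustive 2-cluster oracle: the best 2-partition of {1, 8} by within-
  # cluster sum of squares is the level split itself
  r <- segment_ap(img, init, seed = 1L)
  expect_identical(r$mask$data, arr == 8)
})

test_that("affinity propagation is deterministic and handles uniform input", {
  cs <- small_case()
  r1 <- segment_ap(cs$image, cs$irreg, seed = 5L)
  r2 <- segment_ap(cs$image, cs$irreg, seed = 5L)
  expect_identical(r1$mask$data, r2$mask$data)
  img <- image_volume(array(4, c(4, 4, 2)), c(1, 1, 1))
  init <- binary_mask(array(TRUE, c(4, 4, 2)), c(1, 1, 1))
  ru <- segment_ap(img, init, seed = 1L)
  expect_identical(ru$mask$data, init$data)
  expect_true(ru$params_used$flagged)
})

test_that("the active contour recovers a sharp two-level region exactly", {
  img <- two_level_image()
  init <- binary_mask(array(TRUE, dim(img$data)), img$spacing)
  r <- segment_masac(img, init)
  expect_identical(r$mask$data, two_level_mask(img)$data)
  expect_equal(r$params_used$lam, 3)
})

test_that("the recovered contour is an energy minimum among perturbations", {
  img <- two_level_image(dims = c(5, 5, 1))
  init <- binary_mask(array(TRUE, c(5, 5, 1)), c(1, 1, 1))
  r <- segment_masac(img, init)
  fa <- c(1, 1, 1)
  e_res <- conseg:::cpp_cv_energy(as.numeric(img$data), as.logical(init$data),
                                  as.logical(r$mask$data), dim(img$data), fa, 3)
  # flipping any single voxel of the solution must not lower the energy
  for (v in seq_len(25)) {
    cand <- r$mask$data
    cand[v] <- !cand[v]
    if (!any(cand) || all(cand)) next
    e_cand <- conseg:::cpp_cv_energy(as.numeric(img$data),
                                     as.logical(init$data),
                                     as.logical(cand), dim(img$data), fa, 3)
    expect_gte(e_cand, e_res - 1e-9)
  }
})

test_that("a large smoothness weight shrinks the contour boundary", {
  cs <- small_case(noise = 0.15)
  r_small <- segment_masac(cs$image, cs$rect, masac_params(lam = 0.5))
  r_large <- segment_masac(cs$image, cs$rect, masac_params(lam = 30))
  boundary_area <- function(m) {
    av <- conseg:::mesh_area_volume(m)
    av[1]
  }
  expect_lte(boundary_area(r_large$mask), boundary_area(r_small$mask))
})

test_that("run_all returns containment and agreement on a two-level phantom", {
  img <- two_level_image()
  init <- binary_mask(array(TRUE, dim(img$data)), img$spacing)
  res <- run_all(img, init)
  expect_setequal(names(res), c("MASAC", "AP", "ST", "41MAX"))
  for (r in res) expect_true(all(init$data[r$mask$data]))
  # 41MAX and ST reduce to the same threshold on two-level input
  expect_identical(res$`41MAX`$mask$data, res$ST$mask$data)
})

test_that("every method's mask contains the within-mask maximum or is nonempty", {
  cs <- small_case()
  for (init in list(cs$rect, cs$irreg)) {
    res <- run_all(cs$image, init, seed = 3L)
    imax <- which(cs$image$data == max(cs$image$data[init$data]))[1]
    for (m in c("41MAX", "ST"))
      expect_true(res[[m]]$mask$data[imax])
    for (r in res) {
      expect_gt(sum(r$mask$data), 0)
      expect_true(all(init$data[r$mask$data]))
    }
  }
})
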