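# SUV conversion, discretization, shape, first order, and whole-catalog
# contracts.

test_that("SUV conversion cancels units and is linear", {
  img <- image_volume(array(runif(4^3, 0, 10), c(4, 4, 4)), c(1, 1, 1))
  expect_equal(to_suv(img, suv_params(70, 70))$data, img$data)
  half <- to_suv(img, suv_params(injected_dose = 140, body_weight = 70))
  expect_equal(half$data, img$data / 2)
  expect_error(suv_params(0, 70), "injected_dose")
  expect_error(suv_params(350, -1), "body_weight")
})

test_that("discretization follows the fixed-bin-width rule", {
  img <- image_volume(array(c(0, 0.1, 0.3, 0.6), c(4, 1, 1)), c(1, 1, 1))
  roi <- binary_mask(array(TRUE, c(4, 1, 1)), c(1, 1, 1))
  d <- discretize(img, roi)   # default width 0.25
  expect_identical(as.integer(d$labels), c(1L, 1L, 2L, 3L))
  expect_identical(d$n_levels, 3L)
  expect_equal(formals(discretization_spec)$bin_width, 0.25)
  # single voxel: one level
  roi1 <- binary_mask(array(c(TRUE, FALSE, FALSE, FALSE), c(4, 1, 1)),
                      c(1, 1, 1))
  expect_identical(discretize(img, roi1)$n_levels, 1L)
  img_bad <- image_volume(array(c(0, NA, 1, 2), c(4, 1, 1)), c(1, 1, 1))
  expect_error(discretize(img_bad, roi), "non-finite")
})

test_that("first-order statistics match direct arithmetic", {
  img <- image_volume(array(c(1, 2, 3), c(3, 1, 1)), c(1, 2, 0.5))
  roi <- binary_mask(array(TRUE, c(3, 1, 1)), c(1, 2, 0.5))
  f <- firstorder_features(img, roi)
  expect_equal(unname(f["firstorder_Energy"]), 14)
  expect_equal(unname(f["firstorder_Maximum"]), 3)
  expect_equal(unname(f["firstorder_Mean"]), 2)
  expect_equal(unname(f["firstorder_TotalEnergy"]),
               14 * prod(c(1, 2, 0.5)))
  # TotalEnergy / Energy equals the voxel volume for any ROI
  expect_equal(unname(f["firstorder_TotalEnergy"] / f["firstorder_Energy"]),
               prod(c(1, 2, 0.5)))
})

test_that("percentiles agree with a sort-based linear-interpolation oracle", {
  set.seed(3)
  x <- sample(1:100)
  img <- image_volume(array(x, c(100, 1, 1)), c(1, 1, 1))
  roi <- binary_mask(array(TRUE, c(100, 1, 1)), c(1, 1, 1))
  f <- firstorder_features(img, roi)
  # oracle: sort and interpolate linearly between order statistics
  xs <- sort(x)
  q <- function(p) {
    h <- (length(xs) - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
  }
  expect_equal(unname(f["firstorder_X90Percentile"]), q(0.9))
  expect_equal(unname(f["firstorder_X10Percentile"]), q(0.1))
})

test_that("cuboid mesh volume and surface track the analytic values", {
  arr <- array(FALSE, c(12, 14, 14))
  arr[5:8, 5:10, 5:10] <- TRUE           # 4 x 6 x 6 voxels
  f <- shape_features(binary_mask(arr, c(1, 1, 1)))
  v <- unname(f["shape_MeshVolume"])
  # the isosurface bevels edges and corners, so the mesh volume is slightly
  # below the voxel-count volume (the reference mesh implementations behave
  # the same way on binary masks)
  expect_lt(v, 144)
  expect_gt(v, 144 * 0.94)
  expect_equal(unname(f["shape_VoxelVolume"]), 144)
  a <- unname(f["shape_SurfaceArea"])
  expect_lt(a, 168)
  expect_gt(a, 168 * 0.85)
})

test_that("sphere-like masks have high sphericity, below 1", {
  for (r in c(4, 8)) {
    n <- 2 * r + 6
    c0 <- (n + 1) / 2
    g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
    sp <- array((g$x - c0)^2 + (g$y - c0)^2 + (g$z - c0)^2 <= r^2,
                c(n, n, n))
    f <- shape_features(binary_mask(sp, c(1, 1, 1)))
    expect_lte(unname(f["shape_Sphericity"]), 1)
    expect_gt(unname(f["shape_Sphericity"]), 0.8)
  }
  # a strongly elongated shape is less spherical
  el <- array(FALSE, c(24, 8, 8))
  el[2:23, 4:5, 4:5] <- TRUE
  f_el <- shape_features(binary_mask(el, c(1, 1, 1)))
  expect_lt(unname(f_el["shape_Sphericity"]), 0.7)
  expect_gt(unname(f_el["shape_Elongation"]), 0)
  expect_lt(unname(f_el["shape_Elongation"]), 0.5)
  expect_identical(length(f_el), 14L)
})

test_that("extract_all returns the full 107-feature catalog", {
  cs <- small_case()
  fv <- extract_all(cs$image, cs$gt)
  expect_identical(length(fv), 107L)
  cat <- feature_catalog()
  expect_identical(names(fv), cat$column)
  counts <- table(cat$class)
  expect_identical(counts[["shape"]], 14L)
  expect_identical(counts[["firstorder"]], 18L)
  expect_identical(counts[["glcm"]], 24L)
  expect_identical(counts[["glrlm"]], 16L)
  expect_identical(counts[["glszm"]], 16L)
  expect_identical(counts[["ngtdm"]], 5L)
  expect_identical(counts[["gldm"]], 14L)
  expect_false(any(attr(fv, "invalid")))
})

test_that("flipping the volume along any axis leaves all features unchanged", {
  cs <- small_case(seed = 21L)
  fv <- extract_all(cs$image, cs$gt)
  for (axis in 1:3) {
    flip <- function(a) do.call(`[`, c(list(a), lapply(1:3, function(k)
      if (k == axis) rev(seq_len(dim(a)[k])) else seq_len(dim(a)[k]))))
    img_f <- image_volume(flip(cs$image$data), cs$image$spacing)
    gt_f <- binary_mask(flip(cs$gt$data), cs$gt$spacing)
    fv_f <- extract_all(img_f, gt_f)
    expect_equal(unclass(fv_f), unclass(fv), tolerance = 1e-10)
  }
})

test_that("translation leaves all features unchanged", {
  img <- two_level_image(dims = c(10, 10, 6))
  set.seed(8)
  img$data <- img$data + array(runif(600, 0, 0.5), dim(img$data))
  roi <- binary_mask(img$data >= 8, img$spacing)
  fv <- extract_all(img, roi)
  sh <- function(a) {
    out <- array(a[1], dim(a))
    out[2:dim(a)[1], , ] <- a[1:(dim(a)[1] - 1), , ]
    out
  }
  fv_t <- extract_all(image_volume(sh(img$data), img$spacing),
                      binary_mask(sh(roi$data) == 1, img$spacing))
  expect_equal(unclass(fv_t), unclass(fv), tolerance = 1e-10)
})

test_that("intensity scaling with matched bin width rescales Energy only", {
  cs <- small_case(seed = 33L)
  k <- 3
  fv1 <- extract_all(cs$image, cs$gt, extraction_config(bin_width = 0.25))
  img_k <- image_volume(cs$image$data * k, cs$image$spacing)
  fvk <- extract_all(img_k, cs$gt, extraction_config(bin_width = 0.25 * k))
  expect_equal(unname(fvk["firstorder_Energy"]),
               unname(k^2 * fv1["firstorder_Energy"]))
  expect_equal(unname(fvk["firstorder_Uniformity"]),
               unname(fv1["firstorder_Uniformity"]))
  expect_equal(unname(fvk["firstorder_Entropy"]),
               unname(fv1["firstorder_Entropy"]))
  # texture features are functions of the labels only, hence invariant
  tex <- grep("^(glcm|glrlm|glszm|ngtdm|gldm)_", names(fv1), value = TRUE)
  expect_equal(unclass(fvk[tex]), unclass(fv1[tex]), tolerance = 1e-12)
})

test_that("a one-voxel mask yields defined first order and flagged texture", {
  arr <- array(runif(4^3, 1, 2), c(4, 4, 4))
  img <- image_volume(arr, c(1, 1, 1))
  m <- array(FALSE, c(4, 4, 4))
  m[2, 2, 2] <- TRUE
  fv <- extract_all(img, binary_mask(m, c(1, 1, 1)))
  expect_identical(length(fv), 107L)
  expect_false(is.na(fv["firstorder_Mean"]))
  expect_equal(unname(fv["firstorder_Variance"]), 0)
  inv <- attr(fv, "invalid")
  expect_true(all(inv[grep("^glcm_", names(fv))]))
  expect_true(all(inv[grep("^ngtdm_", names(fv))]))
  # degenerate axis features flagged, run completes
  expect_true(is.na(fv["shape_Elongation"]))
})

test_that("empty or incongruent masks are rejected", {
  img <- image_volume(array(1, c(4, 4, 4)), c(1, 1, 1))
  empty <- binary_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1))
  expect_error(extract_all(img, empty), "empty")
  other <- binary_mask(array(TRUE, c(4, 4, 5)), c(1, 1, 1))
  expect_error(extract_all(img, other), "congruent")
})
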