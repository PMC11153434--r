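# Phantom generation: activity maps, acquisition simulation, initial masks,
# and the seeded suite.

test_that("zero heterogeneity gives a perfectly uniform tumor", {
  g <- grid_spec(c(32, 32, 16), c(0.41, 0.41, 0.5))
  tum <- tumor_spec(center = c(16, 16, 8), radii = c(1, 1, 1),
                    uptake_base = 6, het_amplitude = 0)
  act <- make_activity(g, tum, acquisition_spec())
  vals <- act$image$data[act$gt_mask$data]
  expect_true(all(vals == 6))
})

test_that("voxelized ellipsoid volume approximates the analytic volume", {
  g <- grid_spec(c(32, 32, 16), c(0.5, 0.41, 0.41))
  tum <- tumor_spec(center = c(16, 16, 8), radii = c(1, 1, 1),
                    uptake_base = 6)
  act <- make_activity(g, tum, acquisition_spec())
  v_gt <- sum(act$gt_mask$data) * prod(g$spacing)
  expect_lt(abs(v_gt - 4 * pi / 3) / (4 * pi / 3), 0.15)
})

test_that("activity generation is a pure function of its specs", {
  g <- grid_spec(c(32, 32, 16), c(0.41, 0.41, 0.5))
  tum <- tumor_spec(center = c(16, 16, 8), radii = c(1.1, 0.9, 1),
                    uptake_base = 6, rng_seed = 42L)
  a1 <- make_activity(g, tum, acquisition_spec())
  a2 <- make_activity(g, tum, acquisition_spec())
  expect_identical(a1$image$data, a2$image$data)
  expect_identical(a1$gt_mask$data, a2$gt_mask$data)
})

test_that("a tumor that does not fit is rejected with an explanation", {
  g <- grid_spec(c(16, 16, 8), c(0.41, 0.41, 0.5))
  tum <- tumor_spec(center = c(8, 8, 4), radii = c(5, 5, 5),
                    uptake_base = 6)
  expect_error(make_activity(g, tum, acquisition_spec()), "does not fit")
})

test_that("simulate_pet is the identity with no blur and no noise", {
  img <- image_volume(array(runif(4 * 4 * 4, 1, 5), c(4, 4, 4)), c(1, 1, 1))
  out <- simulate_pet(img, acquisition_spec(psf_fwhm = 0, noise_scale = 0,
                                            post_filter_fwhm = 0))
  expect_identical(out$data, img$data)
})

test_that("blur preserves constant images exactly", {
  img <- image_volume(array(3, c(10, 10, 10)), c(0.4, 0.4, 0.5))
  out <- simulate_pet(img, acquisition_spec(psf_fwhm = 8, noise_scale = 0))
  expect_lt(max(abs(out$data - 3)), 1e-12)
})

test_that("negative activity is rejected", {
  img <- image_volume(array(-1, c(4, 4, 4)), c(1, 1, 1))
  expect_error(simulate_pet(img, acquisition_spec()), "non-negative")
})

test_that("noise has the scaled-Poisson mean and variance grows with scale", {
  act <- image_volume(array(5, c(4, 4, 4)), c(1, 1, 1))
  acq <- acquisition_spec(psf_fwhm = 0, noise_scale = 0.1,
                          post_filter_fwhm = 0)
  reps <- vapply(1:200, function(s) simulate_pet(act, acq, seed = s)$data[1],
                 0)
  # mean of replicates ~ blurred value within 3 standard errors
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 5), 3 * se)
  # empirical variance grows linearly in noise_scale
  scales <- c(0.05, 0.1, 0.2, 0.4)
  vars <- vapply(scales, function(ns) {
    a <- acquisition_spec(psf_fwhm = 0, noise_scale = ns,
                          post_filter_fwhm = 0)
    var(vapply(1:120, function(s) simulate_pet(act, a, seed = s)$data[1], 0))
  }, 0)
  fit <- lm(vars ~ scales)
  expect_gt(coef(fit)[2], 0)
  expect_gt(summary(fit)$r.squared, 0.9)
})

test_that("same seed gives bit-identical simulated images", {
  act <- image_volume(array(runif(5^3, 0.5, 6), c(5, 5, 5)), c(1, 1, 1))
  acq <- acquisition_spec(noise_scale = 0.1)
  expect_identical(simulate_pet(act, acq, seed = 9L)$data,
                   simulate_pet(act, acq, seed = 9L)$data)
})

test_that("rectangular mask with margin 0 is the exact bounding box", {
  cs <- small_case()
  rect0 <- make_initial_masks(cs$gt, "rectangular", params = list(margin = 0))
  idx <- which(cs$gt$data, arr.ind = TRUE)
  expect_equal(sum(rect0$data),
               prod(apply(idx, 2, max) - apply(idx, 2, min) + 1L))
  expect_true(all(rect0$data[cs$gt$data]))
})

test_that("initial masks contain the ground truth; exclusion is honoured", {
  cs <- small_case()
  expect_true(all(cs$rect$data[cs$gt$data]))
  expect_true(all(cs$irreg$data[cs$gt$data]))
  # a distractor overlapping the dilation ring is removed exactly
  excl <- dilate_mask(cs$gt, 3)
  excl <- binary_mask(excl$data & !dilate_mask(cs$gt, 1)$data, cs$gt$spacing)
  m <- make_initial_masks(cs$gt, "irregular", seed = 3L, exclude = excl)
  expect_identical(sum(m$data & excl$data), 0L)
})

test_that("the default suite has 13 cases with volumes in the target range", {
  exp <- cached_experiment(101L)
  suite <- exp$suite
  expect_length(suite$cases, 13L)
  vols <- vapply(suite$cases, gt_volume, 0)
  expect_true(all(vols >= 3.45 & vols <= 56.40))
  # volumes span the range: smallest below 8, largest above 40 cm3
  expect_lt(min(vols), 8)
  expect_gt(max(vols), 40)
  for (case in suite$cases) {
    expect_true(all(case$rect_mask$data[case$gt_mask$data]))
    expect_true(all(case$irreg_mask$data[case$gt_mask$data]))
  }
})

test_that("two suites from the same master seed are identical", {
  cfg <- phantom_config(n_cases = 2L, shape = c(48L, 48L, 24L))
  s1 <- generate_suite(cfg, seed = 11L)
  s2 <- generate_suite(cfg, seed = 11L)
  expect_identical(s1$cases[[1]]$image$data, s2$cases[[1]]$image$data)
  expect_identical(s1$cases[[2]]$irreg_mask$data, s2$cases[[2]]$irreg_mask$data)
  expect_error(generate_suite(phantom_config(n_cases = 0L)), "n_cases")
})
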