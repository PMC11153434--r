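# Synthetic PET lung-tumor phantoms: analytic activity maps with known
# ground truth, blurred with a Gaussian PSF and degraded with scaled
# Poisson noise to stand in for a reconstructed static PET acquisition.

#' Grid specification
#'
#' @param shape integer(3), voxel counts per axis (each >= 8).
#' @param spacing numeric(3), voxel edge lengths in cm per axis.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(shape = c(200L, 200L, 32L),
                      spacing = c(0.41, 0.41, 0.50)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("grid_spec: all shape entries must be >= 8")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("grid_spec: all spacings must be > 0")
  structure(list(shape = shape, spacing = spacing), class = "grid_spec")
}

#' Tumor specification
#'
#' An ellipsoidal lesion with smoothly varying intra-tumor uptake: a seeded
#' Gaussian random field plus a core/rim profile, both scaled by
#' `het_amplitude` so that amplitude 0 gives perfectly uniform uptake.
#'
#' @param center numeric(3), tumor centre in (fractional) grid coordinates.
#' @param radii numeric(3), ellipsoid semi-axes in cm.
#' @param uptake_base baseline tumor uptake (SUV-like).
#' @param het_amplitude SUV amplitude of the heterogeneity texture.
#' @param het_corr_length correlation length of the texture, cm.
#' @param core_contrast relative weight of the hot-core radial profile.
#' @param rng_seed integer seed for the texture field.
#' @return A `tumor_spec` list.
#' @export
tumor_spec <- function(center, radii, uptake_base,
                       het_amplitude = 0.6, het_corr_length = 0.8,
                       core_contrast = 1.0, rng_seed = 1L) {
  if (any(radii <= 0)) stop("tumor_spec: radii must be positive")
  if (het_amplitude < 0 || het_corr_length <= 0)
    stop("tumor_spec: invalid heterogeneity parameters")
  structure(list(center = as.numeric(center), radii = as.numeric(radii),
                 uptake_base = uptake_base, het_amplitude = het_amplitude,
                 het_corr_length = het_corr_length,
                 core_contrast = core_contrast,
                 rng_seed = as.integer(rng_seed)),
            class = "tumor_spec")
}

#' Acquisition specification
#'
#' Imaging degradations applied to the noise-free activity map: Gaussian
#' point-spread function blur followed by scaled Poisson noise, plus scene
#' parameters (background uptake, lung uptake, optional hot distractor blob
#' near the tumor).
#'
#' @param psf_fwhm PSF full width at half maximum, mm (>= 0).
#' @param noise_scale Poisson scaling; the voxel variance equals
#'   `noise_scale` times the blurred activity. 0 disables noise.
#' @param post_filter_fwhm FWHM (mm) of the post-reconstruction Gaussian
#'   filter applied after the noise draw, mimicking the smoothing step of
#'   clinical reconstructions (which leaves PET noise spatially
#'   correlated); 0 disables it.
#' @param background_uptake body background uptake (SUV).
#' @param lung_uptake uptake of the low-activity lung region (SUV).
#' @param hot_distractor `NULL`, or a list with `center` (grid coords),
#'   `radius` (cm) and `uptake` (SUV) describing a nearby high-uptake blob.
#' @return An `acquisition_spec` list.
#' @export
acquisition_spec <- function(psf_fwhm = 6, noise_scale = 0.08,
                             post_filter_fwhm = 4,
                             background_uptake = 1.0, lung_uptake = 0.3,
                             hot_distractor = NULL) {
  if (psf_fwhm < 0) stop("acquisition_spec: psf_fwhm must be >= 0")
  if (noise_scale < 0) stop("acquisition_spec: noise_scale must be >= 0")
  if (post_filter_fwhm < 0)
    stop("acquisition_spec: post_filter_fwhm must be >= 0")
  structure(list(psf_fwhm = psf_fwhm, noise_scale = noise_scale,
                 post_filter_fwhm = post_filter_fwhm,
                 background_uptake = background_uptake,
                 lung_uptake = lung_uptake,
                 hot_distractor = hot_distractor),
            class = "acquisition_spec")
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

# physical coordinates (cm) of voxel centres along one axis, 0-based
axis_coords <- function(n, sp) (seq_len(n) - 1) * sp

# normalized ellipsoid coordinate s(x), evaluated only on the bounding box
# of the ellipsoid (padded by 2 voxels); s <= 1 is inside. Returns the box
# index ranges and the local s values.
ellipsoid_s_local <- function(grid, center, radii) {
  cx <- (center - 1) * grid$spacing
  lo <- pmax(1L, as.integer(floor((cx - radii) / grid$spacing)) + 1L - 2L)
  hi <- pmin(grid$shape,
             as.integer(ceiling((cx + radii) / grid$spacing)) + 1L + 2L)
  ax <- lapply(1:3, function(a)
    (( (lo[a]:hi[a]) - 1) * grid$spacing[a] - cx[a]) / radii[a])
  sq <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  list(lo = lo, hi = hi, s = sqrt(sq))
}

# full-grid logical mask of an ellipsoid (computed locally)
ellipsoid_mask <- function(grid, center, radii) {
  el <- ellipsoid_s_local(grid, center, radii)
  out <- array(FALSE, grid$shape)
  out[el$lo[1]:el$hi[1], el$lo[2]:el$hi[2], el$lo[3]:el$hi[3]] <- el$s <= 1
  binary_mask(out, grid$spacing)
}

#' Build the noise-free activity map and ground-truth mask
#'
#' Composes body background, a low-uptake lung-like region surrounding the
#' lesion, the heterogeneous tumor, and (if specified) a hot distractor
#' blob. The ground truth is the exact voxelized ellipsoid (voxel centre
#' inside), independent of any later blur or segmentation.
#'
#' @param grid a [grid_spec()].
#' @param tumor a [tumor_spec()].
#' @param acq an [acquisition_spec()].
#' @return list with `image` (an `image_volume`, SUV units) and `gt_mask`
#'   (a `binary_mask`).
#' @export
make_activity <- function(grid, tumor, acq) {
  extent <- (grid$shape - 1) * grid$spacing
  cx <- (tumor$center - 1) * grid$spacing
  lo <- cx - tumor$radii
  hi <- cx + tumor$radii
  margin <- 2 * grid$spacing
  if (any(lo < margin) || any(hi > extent - margin))
    stop(sprintf(paste0("make_activity: tumor ellipsoid (centre %s cm, ",
                        "radii %s cm) does not fit inside the grid with a ",
                        "2-voxel margin"),
                 paste(round(cx, 2), collapse = ","),
                 paste(round(tumor$radii, 2), collapse = ",")))
  if (tumor$uptake_base <= acq$background_uptake)
    stop("make_activity: uptake_base must exceed background uptake")

  el <- ellipsoid_s_local(grid, tumor$center, tumor$radii)
  gt <- array(FALSE, grid$shape)
  gt[el$lo[1]:el$hi[1], el$lo[2]:el$hi[2], el$lo[3]:el$hi[3]] <- el$s <= 1
  s_box <- el

  act <- array(acq$background_uptake, grid$shape)
  # lung-like low-uptake region: a large ellipsoid around the lesion
  lung_radii <- pmax(tumor$radii * 2.5, c(3, 3, 3))
  lung_radii <- pmin(lung_radii, extent / 2.4)
  act[ellipsoid_mask(grid, tumor$center, lung_radii)$data] <- acq$lung_uptake

  tumor_vals <- rep(tumor$uptake_base, sum(gt))
  if (tumor$het_amplitude > 0 && sum(gt) > 1) {
    # smooth seeded Gaussian field over the tumor bounding box
    bb <- mask_bbox(binary_mask(gt, grid$spacing), pad = 4L)
    bdim <- bb$hi - bb$lo + 1L
    noise <- with_seed(tumor$rng_seed, rnorm(prod(bdim)))
    sig_vox <- tumor$het_corr_length / grid$spacing
    field <- array(cpp_gauss_blur(noise, bdim, sig_vox), bdim)
    gsub <- crop_to_bbox(gt, bb)
    z <- field[gsub]
    z <- (z - mean(z)) / max(sd(z), 1e-12)
    # s on the GRF bounding box, rebuilt from the local ellipsoid box
    s_full_box <- array(Inf, grid$shape)
    s_full_box[s_box$lo[1]:s_box$hi[1], s_box$lo[2]:s_box$hi[2],
               s_box$lo[3]:s_box$hi[3]] <- s_box$s
    texture <- z + tumor$core_contrast *
      (1 - crop_to_bbox(s_full_box, bb)[gsub]^2)
    tumor_vals <- tumor$uptake_base + tumor$het_amplitude * texture
    tumor_vals <- pmax(tumor_vals, acq$lung_uptake + 0.5)
  }
  act[gt] <- tumor_vals

  hd <- acq$hot_distractor
  if (!is.null(hd)) {
    blob <- ellipsoid_mask(grid, hd$center, rep(hd$radius, 3))$data & !gt
    act[blob] <- pmax(act[blob], hd$uptake)
  }
  list(image = image_volume(act, grid$spacing),
       gt_mask = binary_mask(gt, grid$spacing))
}

#' Simulate PET acquisition from an activity map
#'
#' Gaussian PSF convolution followed by scaled Poisson noise: the noisy
#' voxel is `noise_scale * rpois(blurred / noise_scale)`, so its mean is the
#' blurred value and its variance `noise_scale` times that value.
#'
#' @param activity an `image_volume` of non-negative activity.
#' @param acq an [acquisition_spec()].
#' @param seed integer seed for the noise draw.
#' @return an `image_volume`.
#' @export
simulate_pet <- function(activity, acq, seed = 1L) {
  if (!is.finite(acq$psf_fwhm) || !is.finite(acq$noise_scale))
    stop("simulate_pet: psf_fwhm and noise_scale must be finite")
  if (any(activity$data < 0))
    stop("simulate_pet: activity must be non-negative")
  d <- vol_dims(activity)
  sig_cm <- (acq$psf_fwhm / 10) / (2 * sqrt(2 * log(2)))
  sig_vox <- sig_cm / activity$spacing
  blurred <- if (acq$psf_fwhm > 0) {
    array(cpp_gauss_blur(as.numeric(activity$data), d, sig_vox), d)
  } else {
    activity$data
  }
  out <- if (acq$noise_scale > 0) {
    lam <- blurred / acq$noise_scale
    noisy <- with_seed(seed, rpois(length(lam), lam)) * acq$noise_scale
    array(noisy, d)
  } else {
    blurred
  }
  pf <- if (is.null(acq$post_filter_fwhm)) 0 else acq$post_filter_fwhm
  if (pf > 0) {
    sig_pf <- (pf / 10) / (2 * sqrt(2 * log(2))) / activity$spacing
    out <- array(cpp_gauss_blur(as.numeric(out), d, sig_pf), d)
  }
  image_volume(out, activity$spacing)
}

#' Build a rectangular or irregular initial mask around the ground truth
#'
#' The rectangular style is the ground-truth bounding box dilated by a voxel
#' margin; the irregular style is a dilation of the ground truth with a
#' seeded random perturbation of its boundary, optionally minus an excluded
#' high-uptake region (mirroring a physician cropping out a nearby hot
#' structure).
#'
#' @param gt ground-truth `binary_mask` (nonempty).
#' @param style `"rectangular"` or `"irregular"`.
#' @param params list: `margin` (rectangular, default 3 voxels), `radius`
#'   (irregular dilation, default 2), `jitter` (boundary add/remove
#'   probability, default 0.3).
#' @param seed integer seed for the boundary perturbation.
#' @param exclude optional `binary_mask` to subtract (e.g. a hot
#'   distractor region); applied after the containment union, so the result
#'   is guaranteed disjoint from it.
#' @return a `binary_mask`.
#' @export
make_initial_masks <- function(gt, style = c("rectangular", "irregular"),
                               params = list(), seed = 1L, exclude = NULL) {
  style <- match.arg(style)
  if (!any(gt$data)) stop("make_initial_masks: ground truth mask is empty")
  d <- vol_dims(gt)
  if (style == "rectangular") {
    margin <- if (is.null(params$margin)) 3L else as.integer(params$margin)
    idx <- which(gt$data, arr.ind = TRUE)
    lo <- apply(idx, 2, min) - margin
    hi <- apply(idx, 2, max) + margin
    if (any(lo < 1L) || any(hi > d))
      warning("make_initial_masks: rectangular mask clipped at grid edge")
    lo <- pmax(1L, lo)
    hi <- pmin(d, hi)
    out <- array(FALSE, d)
    out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    m <- binary_mask(out, gt$spacing)
  } else {
    radius <- if (is.null(params$radius)) 2L else as.integer(params$radius)
    jitter <- if (is.null(params$jitter)) 0.3 else params$jitter
    bb <- mask_bbox(gt, pad = radius + 2L)
    gtc <- binary_mask(crop_to_bbox(gt$data, bb), gt$spacing)
    base <- dilate_mask(gtc, radius)
    inner <- if (radius >= 1L) dilate_mask(gtc, radius - 1L) else gtc
    shell_rm <- base$data & !inner$data          # outermost dilation ring
    ring_add <- dilate_mask(gtc, radius + 1L)$data & !base$data
    sub <- base$data
    with_seed(seed, {
      rmv <- which(shell_rm)
      addv <- which(ring_add)
      if (length(rmv)) sub[rmv[runif(length(rmv)) < jitter]] <- FALSE
      if (length(addv)) sub[addv[runif(length(addv)) < jitter]] <- TRUE
    })
    sub <- sub | gtc$data
    out <- array(FALSE, d)
    out[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]] <- sub
    m <- binary_mask(out, gt$spacing)
  }
  if (!is.null(exclude)) {
    stop_if_incongruent(m, exclude, "mask and exclusion region")
    m <- binary_mask(m$data & !exclude$data, gt$spacing)
  }
  m
}

#' Default phantom suite configuration
#'
#' The defaults emulate a static thoracic PET experiment: 13 lesions with
#' heterogeneous uptake on a 200 x 200 in-plane matrix with
#' 0.41 x 0.41 x 0.50 cm voxels, lesion volumes spanning roughly
#' 3.45-56.40 cm3, baseline uptake sampled in 4.5-8.0 SUV over a body
#' background of 1.0 SUV, a 6 mm FWHM PSF, and scaled Poisson noise.
#'
#' @param n_cases number of phantom cases.
#' @param shape,spacing grid geometry (see [grid_spec()]).
#' @param volume_range target range of ground-truth tumor volumes, cm3.
#' @param uptake_range sampling range of baseline tumor uptake, SUV.
#' @param background,lung_uptake scene uptake levels, SUV.
#' @param het_amplitude,het_corr_length,core_contrast tumor texture.
#' @param psf_fwhm PSF FWHM in mm.
#' @param noise_scale Poisson noise scaling.
#' @param post_filter_fwhm post-reconstruction filter FWHM in mm.
#' @param distractor list: `enabled`, `uptake`, `radius` (cm), `gap` (cm).
#' @param rect_margin,irreg_radius,irreg_jitter initial-mask parameters.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(n_cases = 13L,
                           shape = c(200L, 200L, 32L),
                           spacing = c(0.41, 0.41, 0.50),
                           volume_range = c(3.45, 56.40),
                           uptake_range = c(4.5, 8.0),
                           background = 1.0, lung_uptake = 0.3,
                           het_amplitude = 0.6, het_corr_length = 0.8,
                           core_contrast = 1.0,
                           psf_fwhm = 6, noise_scale = 0.08,
                           post_filter_fwhm = 4,
                           distractor = list(enabled = TRUE, uptake = 5.5,
                                             radius = 0.7, gap = 1.0),
                           rect_margin = 3L, irreg_radius = 2L,
                           irreg_jitter = 0.3) {
  cfg <- list(n_cases = as.integer(n_cases), shape = as.integer(shape),
              spacing = spacing, volume_range = volume_range,
              uptake_range = uptake_range, background = background,
              lung_uptake = lung_uptake, het_amplitude = het_amplitude,
              het_corr_length = het_corr_length,
              core_contrast = core_contrast, psf_fwhm = psf_fwhm,
              noise_scale = noise_scale,
              post_filter_fwhm = post_filter_fwhm, distractor = distractor,
              rect_margin = as.integer(rect_margin),
              irreg_radius = as.integer(irreg_radius),
              irreg_jitter = irreg_jitter)
  class(cfg) <- "phantom_config"
  cfg
}

# derive a stream of independent 31-bit sub-seeds from a master seed
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

#' Generate a seeded suite of phantom cases
#'
#' Tumor volumes are placed on a log-spaced ladder across the configured
#' range (with a small seeded jitter), so the suite spans small to large
#' lesions the way the emulated experiment does; all per-case randomness is
#' derived deterministically from the master seed.
#'
#' @param config a [phantom_config()].
#' @param seed master integer seed.
#' @return a `phantom_suite`: list of `phantom_case` objects (fields
#'   `image`, `gt_mask`, `rect_mask`, `irreg_mask`, `provenance`) plus the
#'   config and master seed.
#' @export
generate_suite <- function(config = phantom_config(), seed = 42L) {
  n <- config$n_cases
  if (is.na(n) || n < 1L) stop("generate_suite: n_cases must be >= 1")
  grid <- grid_spec(config$shape, config$spacing)
  case_seeds <- derive_seeds(seed, 4L * n)
  # volumes sampled inside the target range with a margin for voxelization
  vr <- config$volume_range
  vlo <- vr[1] * 1.25
  vhi <- vr[2] * 0.88
  ladder <- exp(seq(log(vlo), log(vhi), length.out = n))
  extent <- (grid$shape - 1) * grid$spacing

  cases <- vector("list", n)
  for (i in seq_len(n)) {
    s_case <- case_seeds[i]
    pars <- with_seed(s_case, {
      list(vol = ladder[i] * exp(runif(1, -0.06, 0.06)),
           aspect = runif(3, 0.8, 1.25),
           cjit = c(runif(2, -1, 1), runif(1, -0.5, 0.5)),
           base = runif(1, config$uptake_range[1], config$uptake_range[2]),
           ddir = sample(c(1, 3, 5, 7), 1) * pi / 4)
    })
    aspect <- pars$aspect / prod(pars$aspect)^(1 / 3)
    r0 <- (3 * pars$vol / (4 * pi))^(1 / 3)
    radii <- r0 * aspect
    center_cm <- extent / 2 + pars$cjit
    center <- center_cm / grid$spacing + 1
    tum <- tumor_spec(center = center, radii = radii,
                      uptake_base = pars$base,
                      het_amplitude = config$het_amplitude,
                      het_corr_length = config$het_corr_length,
                      core_contrast = config$core_contrast,
                      rng_seed = case_seeds[n + i])
    hd <- NULL
    if (isTRUE(config$distractor$enabled)) {
      # place the hot blob along an in-plane diagonal (where a bounding-box
      # mask has spare room), one gap beyond the lesion surface
      u <- c(cos(pars$ddir), sin(pars$ddir), 0)
      r_dir <- 1 / sqrt(sum((u / c(radii[1:2], 1))[1:2]^2))
      dist_cm <- r_dir + config$distractor$gap + config$distractor$radius
      hd <- list(center = (center_cm + u * dist_cm) / grid$spacing + 1,
                 radius = config$distractor$radius,
                 uptake = config$distractor$uptake)
    }
    acq <- acquisition_spec(psf_fwhm = config$psf_fwhm,
                            noise_scale = config$noise_scale,
                            post_filter_fwhm = config$post_filter_fwhm,
                            background_uptake = config$background,
                            lung_uptake = config$lung_uptake,
                            hot_distractor = hd)
    act <- make_activity(grid, tum, acq)
    img <- simulate_pet(act$image, acq, seed = case_seeds[2L * n + i])
    # exclusion covers the distractor and its partial-volume halo, the way
    # a physician crops out a hot structure generously; the margin is
    # Euclidean and smaller than the gap, so it can never reach the lesion
    excl <- if (!is.null(hd))
      ellipsoid_mask(grid, hd$center, rep(hd$radius + 0.85, 3))
    else NULL
    rect <- make_initial_masks(act$gt_mask, "rectangular",
                               params = list(margin = config$rect_margin))
    irreg <- make_initial_masks(act$gt_mask, "irregular",
                                params = list(radius = config$irreg_radius,
                                              jitter = config$irreg_jitter),
                                seed = case_seeds[3L * n + i],
                                exclude = excl)
    cases[[i]] <- structure(
      list(image = img, gt_mask = act$gt_mask, rect_mask = rect,
           irreg_mask = irreg,
           provenance = list(case = i, seed = s_case, tumor = tum,
                             acquisition = acq, grid = grid)),
      class = "phantom_case")
  }
  structure(list(cases = cases, config = config, seed = seed),
            class = "phantom_suite")
}

#' Ground-truth volume of a phantom case, cm3
#' @param case a `phantom_case`.
#' @return scalar volume (voxel count times voxel volume).
#' @export
gt_volume <- function(case) {
  sum(case$gt_mask$data) * voxel_volume(case$gt_mask)
}
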