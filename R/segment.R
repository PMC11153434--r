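# Four automatic PET tumor segmentation methods, each operating strictly
# inside a user-supplied initial mask, plus a driver running all four.

new_segmentation_result <- function(method, mask, params_used,
                                    mask_style = NA_character_) {
  structure(list(method = method, mask_style = mask_style, mask = mask,
                 params_used = params_used),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation_result [%s]: %d voxels%s\n", x$method,
              sum(x$mask$data),
              if (isTRUE(x$params_used$flagged)) " (flagged)" else ""))
  invisible(x)
}

check_seg_inputs <- function(image, init) {
  stop_if_incongruent(image, init, "image and initial mask")
  if (!any(init$data)) stop("initial mask is empty")
  if (any(!is.finite(image$data[init$data])))
    stop("image contains non-finite values inside the initial mask")
  invisible(TRUE)
}

# keep the largest 26-connected component, restricted to the initial mask;
# the labelling runs on the initial-mask bounding box only (anything outside
# is empty by construction)
postprocess_lcc <- function(mask_arr, init) {
  sel <- mask_arr & init$data
  if (!any(sel)) return(binary_mask(sel, init$spacing))
  bb <- mask_bbox(init)
  sub <- largest_component(binary_mask(crop_to_bbox(sel, bb), init$spacing))
  out <- array(FALSE, vol_dims(init))
  out[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]] <- sub$data
  binary_mask(out, init$spacing)
}

# work on the subvolume spanned by the initial mask plus padding; behaviour
# is unchanged because voxels outside the padded box can never contribute
seg_crop <- function(image, init, pad = 1L) {
  bb <- mask_bbox(init, pad = pad)
  list(image = image_volume(crop_to_bbox(image$data, bb), image$spacing),
       init = binary_mask(crop_to_bbox(init$data, bb), init$spacing),
       bb = bb, full_dims = vol_dims(init), spacing = init$spacing)
}

seg_uncrop <- function(mask, ctx) {
  arr <- array(FALSE, ctx$full_dims)
  arr[ctx$bb$lo[1]:ctx$bb$hi[1], ctx$bb$lo[2]:ctx$bb$hi[2],
      ctx$bb$lo[3]:ctx$bb$hi[3]] <- mask$data
  binary_mask(arr, ctx$spacing)
}

#' Fixed-threshold segmentation at a fraction of the maximum uptake
#'
#' Retains voxels of the initial mask whose intensity is at least
#' `fraction` times the maximum intensity inside the mask (the classical
#' 41\%-of-SUVmax rule by default), then keeps the largest connected
#' component.
#'
#' @param image an `image_volume`.
#' @param init initial `binary_mask`.
#' @param fraction threshold fraction of the within-mask maximum.
#' @return a `segmentation_result`.
#' @export
segment_41max <- function(image, init, fraction = 0.41) {
  check_seg_inputs(image, init)
  if (fraction <= 0 || fraction > 1)
    stop("segment_41max: fraction must be in (0, 1]")
  ctx <- seg_crop(image, init, pad = 1L)
  mx <- max(ctx$image$data[ctx$init$data])
  thr <- fraction * mx
  sel <- ctx$init$data & ctx$image$data >= thr
  if (!any(sel)) stop("segment_41max: empty result after thresholding")
  res <- seg_uncrop(postprocess_lcc(sel, ctx$init), ctx)
  new_segmentation_result("41MAX", res,
                          list(fraction = fraction, threshold = thr,
                               max_uptake = mx))
}

#' Parameters for contrast-oriented thresholding
#'
#' @param a weight on the mean of the high-uptake isocontour region.
#' @param b weight on the local background estimate.
#' @param iso_fraction isocontour fraction defining the high-uptake region.
#' @param bg_shell inner/outer dilation radii (voxels) of the background
#'   shell around the current contour.
#' @param max_iter,tol iteration control.
#' @return an `st_params` list.
#' @export
st_params <- function(a = 0.5, b = 0.5, iso_fraction = 0.70,
                      bg_shell = c(2L, 4L), max_iter = 30L, tol = 1e-4) {
  if (a < 0 || b < 0) stop("st_params: a and b must be >= 0")
  if (iso_fraction <= 0 || iso_fraction >= 1)
    stop("st_params: iso_fraction must be in (0, 1)")
  list(a = a, b = b, iso_fraction = iso_fraction,
       bg_shell = as.integer(bg_shell), max_iter = as.integer(max_iter),
       tol = tol)
}

#' Contrast-oriented (Schaefer-type) adaptive thresholding
#'
#' Iterates a threshold `T = a * mean(high-uptake isocontour region) +
#' b * background`, where the background is the mean intensity in a shell
#' between the `bg_shell` dilations of the current contour. Stops when the
#' contour is unchanged, the threshold moves less than `tol`, or `max_iter`
#' is reached (then flagged as non-converged).
#'
#' @inheritParams segment_41max
#' @param p an [st_params()] list.
#' @return a `segmentation_result`.
#' @export
segment_st <- function(image, init, p = st_params()) {
  check_seg_inputs(image, init)
  ctx <- seg_crop(image, init, pad = p$bg_shell[2] + 1L)
  image <- ctx$image
  init <- ctx$init
  cur <- largest_component(init)
  t_prev <- Inf
  converged <- FALSE
  t_cur <- NA_real_
  for (it in seq_len(p$max_iter)) {
    mx <- max(image$data[cur$data])
    iso <- cur$data & image$data >= p$iso_fraction * mx
    hi_mean <- mean(image$data[iso])
    inner <- dilate_mask(cur, p$bg_shell[1])
    outer <- dilate_mask(cur, p$bg_shell[2])
    shell <- outer$data & !inner$data
    if (!any(shell)) {
      # mask fills the (cropped) grid: take the non-isocontour part of the
      # mask as local background; on a fully uniform mask this degenerates
      # to the high-region mean, reproducing the uniform-input behaviour
      shell <- init$data & !iso
    }
    bg <- if (any(shell)) mean(image$data[shell]) else hi_mean
    t_cur <- p$a * hi_mean + p$b * bg
    nxt_arr <- init$data & image$data >= t_cur
    if (!any(nxt_arr)) {
      # threshold overshot everything: keep the maximum voxel
      nxt_arr <- init$data & image$data >= max(image$data[init$data])
    }
    nxt <- postprocess_lcc(nxt_arr, init)
    if (identical(nxt$data, cur$data) || abs(t_cur - t_prev) < p$tol) {
      cur <- nxt
      converged <- TRUE
      break
    }
    cur <- nxt
    t_prev <- t_cur
  }
  new_segmentation_result("ST", seg_uncrop(cur, ctx),
                          c(p, list(threshold = t_cur, iterations = it,
                                    converged = converged,
                                    flagged = !converged)))
}

#' Parameters for affinity propagation segmentation
#'
#' @param damping message damping factor in `[0.5, 1)`.
#' @param max_iter,conv_iter iteration budget and stability window.
#' @param spatial_weight weight of scaled voxel coordinates in the feature
#'   vector (0 = intensity only).
#' @param max_voxels seeded subsampling threshold; above it, clustering runs
#'   on a sample and labels propagate to the rest by nearest intensity.
#' @param foreground how the clusters are binarized into the segmentation:
#'   `"hot_classes"` (default) keeps every cluster whose exemplar intensity
#'   exceeds `hot_fraction` of the within-mask maximum (the high-uptake
#'   grouping); `"max_uptake"` keeps only the cluster containing the
#'   highest-uptake voxel; `"largest"` keeps the cluster with the most
#'   voxels, which in loose initial masks can be a background grouping.
#' @param hot_fraction fraction of the within-mask maximum above which a
#'   cluster's exemplar counts as high-uptake (used by `"hot_classes"`).
#' @return an `ap_params` list.
#' @export
ap_params <- function(damping = 0.9, max_iter = 500L, conv_iter = 25L,
                      spatial_weight = 0, max_voxels = 800L,
                      foreground = c("hot_classes", "max_uptake",
                                     "largest"), hot_fraction = 0.5) {
  if (damping < 0.5 || damping >= 1)
    stop("ap_params: damping must be in [0.5, 1)")
  if (hot_fraction <= 0 || hot_fraction >= 1)
    stop("ap_params: hot_fraction must be in (0, 1)")
  list(damping = damping, max_iter = as.integer(max_iter),
       conv_iter = as.integer(conv_iter), spatial_weight = spatial_weight,
       max_voxels = as.integer(max_voxels),
       foreground = match.arg(foreground), hot_fraction = hot_fraction)
}

# Otsu threshold over a numeric vector (exhaustive over sorted midpoints)
otsu_threshold <- function(x) {
  xs <- sort(unique(x))
  if (length(xs) < 2L) return(xs[1])
  cands <- (xs[-1] + xs[-length(xs)]) / 2
  best <- cands[1]
  best_var <- Inf
  for (t in cands) {
    lo <- x[x < t]
    hi <- x[x >= t]
    wv <- (if (length(lo) > 1) (length(lo) - 1) * stats::var(lo) else 0) +
      (if (length(hi) > 1) (length(hi) - 1) * stats::var(hi) else 0)
    if (wv < best_var) {
      best_var <- wv
      best <- t
    }
  }
  best
}

#' Affinity propagation segmentation
#'
#' Clusters voxel feature vectors (intensity, optionally scaled coordinates)
#' inside the initial mask by affinity propagation with similarity equal to
#' negative squared feature distance and preference equal to the median
#' similarity. The largest cluster by voxel count is taken as foreground,
#' then the largest connected component is retained. If message passing does
#' not converge, falls back to a two-class Otsu intensity split (flagged).
#'
#' @inheritParams segment_41max
#' @param p an [ap_params()] list.
#' @param seed integer seed for the voxel subsample.
#' @return a `segmentation_result`.
#' @export
segment_ap <- function(image, init, p = ap_params(), seed = 1L) {
  check_seg_inputs(image, init)
  ctx <- seg_crop(image, init, pad = 1L)
  image <- ctx$image
  init <- ctx$init
  idx <- which(init$data)
  vals <- image$data[idx]
  if (diff(range(vals)) < 1e-12) {
    # degenerate: one intensity level, a single cluster
    return(new_segmentation_result(
      "AP", seg_uncrop(largest_component(init), ctx),
      c(p, list(flagged = TRUE, degenerate = "uniform"))))
  }
  sub <- seq_along(idx)
  subsampled <- length(idx) > p$max_voxels
  if (subsampled)
    sub <- sort(with_seed(seed, sample.int(length(idx), p$max_voxels)))
  feats <- matrix(vals[sub], ncol = 1)
  if (p$spatial_weight > 0) {
    d <- vol_dims(image)
    ai <- arrayInd(idx[sub], d)
    feats <- cbind(feats, p$spatial_weight * ai %*% diag(image$spacing))
  }
  sim <- -as.matrix(stats::dist(feats))^2
  pref <- stats::median(sim[upper.tri(sim)])
  diag(sim) <- pref
  # break exact similarity ties (identical intensities make the message
  # passing degenerate); the jitter is seeded and far below data scale
  eps_scale <- 1e-9 * max(abs(pref), 1)
  jit <- with_seed(seed + 1L,
                   matrix(runif(length(sim)), nrow(sim)))
  sim <- sim + eps_scale * (jit + t(jit))
  fit <- cpp_affinity_propagation(sim, p$damping, p$max_iter, p$conv_iter)
  flagged <- FALSE
  if (!fit$converged || all(is.na(fit$assignment))) {
    # fall back to a two-class intensity split, keeping the hot class
    flagged <- TRUE
    thr <- otsu_threshold(vals)
    member <- vals >= thr
    fg <- idx[member]
  } else {
    assign_sub <- fit$assignment
    if (p$foreground == "largest") {
      sizes <- table(assign_sub)
      chosen <- as.integer(names(sizes)[which.max(sizes)])
    } else if (p$foreground == "max_uptake") {
      chosen <- assign_sub[which.max(feats[, 1])]
    } else {
      # hot classes: clusters whose exemplar intensity lies above the
      # midpoint of the within-mask intensity range (assignments are
      # indices into the sampled feature rows, so exemplar intensity =
      # feats[ex, 1])
      ex <- sort(unique(assign_sub))
      ex_int <- feats[ex, 1]
      cut <- p$hot_fraction * max(vals)
      chosen <- ex[ex_int > cut]
      if (!length(chosen)) chosen <- ex[which.max(ex_int)]
    }
    member_sub <- assign_sub %in% chosen
    if (subsampled) {
      # propagate labels to unsampled voxels by nearest sampled intensity
      svals <- vals[sub]
      o <- order(svals)
      so <- svals[o]
      mo <- member_sub[o]
      pos <- findInterval(vals, so, all.inside = TRUE)
      pos2 <- pmin(pos + 1L, length(so))
      pick <- ifelse(abs(vals - so[pos]) <= abs(so[pos2] - vals), pos, pos2)
      member <- mo[pick]
      member[sub] <- member_sub
    } else {
      member <- member_sub
    }
    fg <- idx[member]
  }
  sel <- array(FALSE, vol_dims(image))
  sel[fg] <- TRUE
  res <- postprocess_lcc(sel, init)
  new_segmentation_result("AP", seg_uncrop(res, ctx),
                          c(p, list(flagged = flagged,
                                    subsampled = subsampled,
                                    converged = fit$converged)))
}

#' Parameters for the region-based active contour
#'
#' @param lam boundary-length penalty weight (default 3).
#' @param max_iter maximum ICM sweeps.
#' @param tol energy-change stopping tolerance.
#' @return a `masac_params` list.
#' @export
masac_params <- function(lam = 3, max_iter = 100L, tol = 1e-6) {
  if (lam <= 0) stop("masac_params: lam must be > 0")
  list(lam = lam, max_iter = as.integer(max_iter), tol = tol)
}

#' Region-based active-contour segmentation
#'
#' Minimises a two-region piecewise-constant (Chan-Vese type) energy with a
#' boundary-length penalty weighted by `lam`, restricted to the initial
#' mask and initialised from the 41\%-of-maximum contour. Degenerate
#' evolutions (empty or mask-filling) return the initialisation, flagged.
#'
#' @inheritParams segment_41max
#' @param p a [masac_params()] list.
#' @return a `segmentation_result`.
#' @export
segment_masac <- function(image, init, p = masac_params()) {
  check_seg_inputs(image, init)
  ctx <- seg_crop(image, init, pad = 1L)
  image <- ctx$image
  init <- ctx$init
  start <- segment_41max(image, init)$mask
  d <- vol_dims(image)
  sp <- image$spacing
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  vals <- image$data[init$data]
  if (diff(range(vals)) < 1e-12) {
    return(new_segmentation_result(
      "MASAC", seg_uncrop(largest_component(init), ctx),
      c(p, list(flagged = TRUE, degenerate = "uniform"))))
  }
  fit <- cpp_chanvese_icm(as.numeric(image$data), as.logical(init$data),
                          as.logical(start$data), d, face_area, p$lam,
                          p$max_iter, p$tol)
  if (isTRUE(fit$degenerate) || !any(fit$mask)) {
    return(new_segmentation_result(
      "MASAC", seg_uncrop(start, ctx),
      c(p, list(flagged = TRUE, degenerate = "collapse"))))
  }
  res <- postprocess_lcc(array(fit$mask, d), init)
  new_segmentation_result("MASAC", seg_uncrop(res, ctx),
                          c(p, list(iterations = fit$iterations,
                                    converged = fit$converged,
                                    energy = fit$energy, flagged = FALSE)))
}

#' Run the four individual segmentation methods under one initial mask
#'
#' Individual failures are caught and recorded; an error is raised only if
#' all four methods fail.
#'
#' @inheritParams segment_41max
#' @param params optional list with elements `st`, `ap`, `masac`,
#'   `fraction` overriding method parameters.
#' @param seed integer seed (used by affinity propagation subsampling).
#' @return named list of `segmentation_result` objects (may be shorter than
#'   four if methods failed), with attribute `failures` naming failed
#'   methods.
#' @export
run_all <- function(image, init, params = list(), seed = 1L) {
  check_seg_inputs(image, init)
  fraction <- if (is.null(params$fraction)) 0.41 else params$fraction
  st_p <- if (is.null(params$st)) st_params() else params$st
  ap_p <- if (is.null(params$ap)) ap_params() else params$ap
  ms_p <- if (is.null(params$masac)) masac_params() else params$masac
  runners <- list(
    MASAC = function() segment_masac(image, init, ms_p),
    AP = function() segment_ap(image, init, ap_p, seed = seed),
    ST = function() segment_st(image, init, st_p),
    `41MAX` = function() segment_41max(image, init, fraction))
  out <- list()
  failures <- character()
  for (m in names(runners)) {
    r <- tryCatch(runners[[m]](), error = function(e) e)
    if (inherits(r, "error")) {
      failures <- c(failures, m)
      warning(sprintf("run_all: %s failed: %s", m, conditionMessage(r)))
    } else {
      out[[m]] <- r
    }
  }
  if (!length(out)) stop("run_all: all four segmentation methods failed")
  attr(out, "failures") <- failures
  out
}
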