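#' PET image volume
#'
#' A 3-D scalar grid with physical voxel spacing. Intensities are assumed to
#' be standardized uptake values (SUV) once [to_suv()] has been applied (or
#' when the volume was generated directly in SUV units, as the phantom
#' generator does).
#'
#' @param data 3-D numeric array.
#' @param spacing numeric(3), voxel edge lengths in cm per axis.
#' @param suv logical, whether intensities are already in SUV units.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, suv = TRUE) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("image_volume: 'data' must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("image_volume: 'spacing' must be three positive voxel sizes (cm)")
  structure(list(data = data, spacing = spacing, suv = isTRUE(suv)),
            class = "image_volume")
}

#' Binary mask aligned to an image volume
#'
#' @param data 3-D logical (or coercible) array.
#' @param spacing numeric(3), voxel edge lengths in cm per axis.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("binary_mask: 'data' must be a 3-D array")
  storage.mode(data) <- "logical"
  data[is.na(data)] <- FALSE
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("binary_mask: 'spacing' must be three positive voxel sizes (cm)")
  structure(list(data = data, spacing = spacing), class = "binary_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image_volume %s, spacing %s cm, range [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask %s, spacing %s cm, %d voxels set\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"), sum(x$data)))
  invisible(x)
}

vol_dims <- function(x) dim(x$data)

voxel_volume <- function(x) prod(x$spacing)

#' Check that two volumes/masks share grid and spacing
#' @param a,b `image_volume` or `binary_mask` objects.
#' @return logical.
#' @export
congruent <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < 1e-9)
}

stop_if_incongruent <- function(a, b, what = "inputs") {
  if (!congruent(a, b))
    stop(sprintf("%s are not on congruent grids (dims/spacing differ)", what))
  invisible(TRUE)
}

#' Morphological dilation of a mask
#'
#' Chebyshev-ball (26-neighbourhood) dilation of integer radius `r` voxels.
#'
#' @param mask a `binary_mask`.
#' @param r non-negative integer radius in voxels.
#' @return dilated `binary_mask`.
#' @export
dilate_mask <- function(mask, r) {
  r <- as.integer(r)
  if (r < 0L) stop("dilate_mask: radius must be >= 0")
  d <- vol_dims(mask)
  out <- cpp_dilate_cheb(as.logical(mask$data), d, r)
  binary_mask(array(out, d), mask$spacing)
}

#' Connected components of a mask (26-connectivity)
#'
#' @param mask a `binary_mask`.
#' @return integer array of component labels, 0 = background.
#' @export
label_components <- function(mask) {
  d <- vol_dims(mask)
  array(cpp_label_components(as.logical(mask$data), d), d)
}

#' Largest connected component of a mask
#'
#' @param mask a `binary_mask`.
#' @return `binary_mask` keeping only the largest 26-connected component
#'   (first-labelled wins ties, which is deterministic in scan order).
#' @export
largest_component <- function(mask) {
  if (!any(mask$data)) return(mask)
  lab <- label_components(mask)
  tab <- tabulate(lab[lab > 0L])
  keep <- which.max(tab)
  binary_mask(lab == keep, mask$spacing)
}

# bounding box (list of index ranges) of a mask, optionally padded
mask_bbox <- function(mask, pad = 0L) {
  idx <- which(mask$data, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask_bbox: empty mask")
  d <- vol_dims(mask)
  lo <- pmax(1L, apply(idx, 2, min) - pad)
  hi <- pmin(d, apply(idx, 2, max) + pad)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

crop_to_bbox <- function(arr, bb) {
  arr[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
}
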