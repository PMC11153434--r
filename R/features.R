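# Radiomic feature catalog: 107 features in seven classes, computed on SUV
# images discretized with a fixed bin width, following the public
# IBSI-aligned catalog's definitions (with its documented deviations).

.eps <- 2.220446e-16

.catalog <- list(
  shape = c("Elongation", "Flatness", "LeastAxisLength", "MajorAxisLength",
            "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
            "Maximum2DDiameterSlice", "Maximum3DDiameter", "MeshVolume",
            "MinorAxisLength", "Sphericity", "SurfaceArea",
            "SurfaceVolumeRatio", "VoxelVolume"),
  firstorder = c("X10Percentile", "X90Percentile", "Energy", "Entropy",
                 "InterquartileRange", "Kurtosis", "Maximum",
                 "MeanAbsoluteDeviation", "Mean", "Median", "Minimum",
                 "Range", "RobustMeanAbsoluteDeviation", "RootMeanSquared",
                 "Skewness", "TotalEnergy", "Uniformity", "Variance"),
  glcm = c("Autocorrelation", "ClusterProminence", "ClusterShade",
           "ClusterTendency", "Contrast", "Correlation",
           "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
           "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2", "InverseVariance",
           "JointAverage", "JointEnergy", "JointEntropy", "MCC",
           "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares"),
  glrlm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
            "GrayLevelVariance", "HighGrayLevelRunEmphasis",
            "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
            "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
            "RunEntropy", "RunLengthNonUniformity",
            "RunLengthNonUniformityNormalized", "RunPercentage",
            "RunVariance", "ShortRunEmphasis",
            "ShortRunHighGrayLevelEmphasis", "ShortRunLowGrayLevelEmphasis"),
  glszm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
            "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
            "LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
            "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
            "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
            "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
            "SmallAreaLowGrayLevelEmphasis", "ZoneEntropy", "ZonePercentage",
            "ZoneVariance"),
  ngtdm = c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength"),
  gldm = c("DependenceEntropy", "DependenceNonUniformity",
           "DependenceNonUniformityNormalized", "DependenceVariance",
           "GrayLevelNonUniformity", "GrayLevelVariance",
           "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
           "LargeDependenceHighGrayLevelEmphasis",
           "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
           "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
           "SmallDependenceLowGrayLevelEmphasis"))

#' The 107-feature radiomic catalog
#'
#' @return data.frame with columns `class`, `name` and `column` (the stable
#'   column label `class_name` used in feature tables), in the fixed
#'   extraction order: 14 shape, 18 first order, 24 GLCM, 16 GLRLM,
#'   16 GLSZM, 5 NGTDM and 14 GLDM features.
#' @export
feature_catalog <- function() {
  cls <- rep(names(.catalog), lengths(.catalog))
  nm <- unlist(.catalog, use.names = FALSE)
  data.frame(class = cls, name = nm, column = paste(cls, nm, sep = "_"),
             stringsAsFactors = FALSE)
}

#' SUV conversion parameters
#'
#' @param injected_dose total injected dose (must be > 0).
#' @param body_weight patient body weight (must be > 0).
#' @return a `suv_params` list.
#' @export
suv_params <- function(injected_dose, body_weight) {
  if (!is.finite(injected_dose) || injected_dose <= 0)
    stop("suv_params: injected_dose must be > 0")
  if (!is.finite(body_weight) || body_weight <= 0)
    stop("suv_params: body_weight must be > 0")
  list(injected_dose = injected_dose, body_weight = body_weight)
}

#' Convert a concentration image to standardized uptake values
#'
#' `SUV = concentration * body_weight / injected_dose` in consistent units;
#' the transform is linear in the input.
#'
#' @param image an `image_volume` of tracer concentration.
#' @param p a [suv_params()] list.
#' @return an `image_volume` flagged as SUV.
#' @export
to_suv <- function(image, p) {
  out <- image$data * (p$body_weight / p$injected_dose)
  image_volume(out, image$spacing, suv = TRUE)
}

#' Fixed-bin-width discretization specification
#'
#' @param bin_width bin width in SUV units (default 0.25). Bin edges are
#'   anchored at the ROI minimum.
#' @return a `discretization_spec` list.
#' @export
discretization_spec <- function(bin_width = 0.25) {
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("discretization_spec: bin_width must be > 0")
  list(bin_width = bin_width)
}

#' Discretize ROI intensities into fixed-width gray-level bins
#'
#' `label(x) = floor((x - min_ROI) / bin_width) + 1`, with the top value
#' clamped into the last bin; labels start at 1 (voxels outside the ROI get
#' label 0).
#'
#' @param image an `image_volume`.
#' @param roi a nonempty `binary_mask`.
#' @param d a [discretization_spec()].
#' @return list with `labels` (integer array, 0 outside the ROI) and
#'   `n_levels`.
#' @export
discretize <- function(image, roi, d = discretization_spec()) {
  stop_if_incongruent(image, roi, "image and ROI")
  if (!any(roi$data)) stop("discretize: ROI is empty")
  vals <- image$data[roi$data]
  if (any(!is.finite(vals)))
    stop("discretize: non-finite intensities inside the ROI")
  lo <- min(vals)
  lab <- as.integer(floor((vals - lo) / d$bin_width)) + 1L
  n_levels <- max(lab)
  lab <- pmin(lab, n_levels)
  labels <- array(0L, vol_dims(image))
  labels[roi$data] <- lab
  list(labels = labels, n_levels = n_levels, bin_width = d$bin_width,
       origin = lo)
}

#' Extraction configuration
#'
#' @param bin_width fixed SUV bin width for discretization.
#' @param suv optional [suv_params()]; `NULL` when the image is already in
#'   SUV units (no conversion applied).
#' @param gldm_alpha dependence tolerance on `|level difference|`.
#' @return an `extraction_config` list.
#' @export
extraction_config <- function(bin_width = 0.25, suv = NULL, gldm_alpha = 0L) {
  list(bin_width = bin_width, suv = suv, gldm_alpha = as.integer(gldm_alpha))
}

# assemble a named feature vector for one class, marking non-finite or
# explicitly flagged entries invalid
as_feature_class <- function(values, class) {
  nm <- .catalog[[class]]
  stopifnot(all(nm %in% names(values)))
  v <- unlist(values[nm])
  invalid <- !is.finite(v)
  v[invalid] <- NA_real_
  names(v) <- paste(class, nm, sep = "_")
  attr(v, "invalid") <- invalid
  v
}

#' Extract the full 107-feature vector
#'
#' Applies SUV conversion (if configured), crops to the mask bounding box,
#' discretizes with the fixed bin width, and runs all seven class
#' extractors. No resampling and no image filters are applied. Features that
#' are undefined on the input (e.g. correlation-type features on a
#' single-gray-level ROI, or anisotropy measures on a single voxel) are
#' returned as `NA` and marked in the `invalid` attribute.
#'
#' @param image an `image_volume`.
#' @param mask a nonempty `binary_mask` congruent with `image`.
#' @param config an [extraction_config()].
#' @return named numeric vector of length 107 (class `feature_vector`) with
#'   attributes `invalid` (logical) and `n_voxels`.
#' @export
extract_all <- function(image, mask, config = extraction_config()) {
  stop_if_incongruent(image, mask, "image and mask")
  if (!any(mask$data)) stop("extract_all: mask is empty")
  if (!is.null(config$suv)) image <- to_suv(image, config$suv)

  # crop to the mask bounding box (texture neighbourhoods are unaffected:
  # everything outside the mask is excluded anyway)
  bb <- mask_bbox(mask, pad = 1L)
  img <- image_volume(crop_to_bbox(image$data, bb), image$spacing)
  roi <- binary_mask(crop_to_bbox(mask$data, bb), mask$spacing)

  d <- discretization_spec(config$bin_width)
  disc <- discretize(img, roi, d)

  out <- c(
    as_feature_class(.shape_features(roi), "shape"),
    as_feature_class(.firstorder_features(img, roi, disc), "firstorder"),
    as_feature_class(.glcm_features(disc), "glcm"),
    as_feature_class(.glrlm_features(disc), "glrlm"),
    as_feature_class(.glszm_features(disc), "glszm"),
    as_feature_class(.ngtdm_features(disc), "ngtdm"),
    as_feature_class(.gldm_features(disc, config$gldm_alpha), "gldm"))
  invalid <- !is.finite(out) | is.na(out)
  stopifnot(length(out) == 107L)
  structure(out, invalid = invalid, n_voxels = sum(roi$data),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("feature_vector: 107 features, %d invalid, %d voxels\n",
              sum(attr(x, "invalid")), attr(x, "n_voxels")))
  invisible(x)
}

#' Shape features (14)
#' @param mask a nonempty `binary_mask`.
#' @return named numeric vector of the 14 shape features.
#' @export
shape_features <- function(mask) {
  if (!any(mask$data)) stop("shape_features: mask is empty")
  as_feature_class(.shape_features(mask), "shape")
}

#' First-order statistics (18)
#' @param image an `image_volume`.
#' @param roi a nonempty `binary_mask`.
#' @param d a [discretization_spec()] (used by Entropy and Uniformity).
#' @return named numeric vector of the 18 first-order features.
#' @export
firstorder_features <- function(image, roi, d = discretization_spec()) {
  disc <- discretize(image, roi, d)
  as_feature_class(.firstorder_features(image, roi, disc), "firstorder")
}

#' Texture features by matrix family
#'
#' Gray-level matrices are built in 3-D over the 13 unique direction
#' offsets of the 26-neighbourhood at distance 1; GLCM matrices are
#' symmetrized and features averaged over directions (unweighted), GLRLM
#' features are averaged over directions, and GLSZM/NGTDM/GLDM are
#' direction-free. Voxels outside the ROI never contribute to counts.
#'
#' @param image an `image_volume`.
#' @param roi a nonempty `binary_mask`.
#' @param d a [discretization_spec()].
#' @param alpha GLDM dependence tolerance.
#' @return named numeric vector (24 GLCM / 16 GLRLM / 16 GLSZM / 5 NGTDM /
#'   14 GLDM features).
#' @export
glcm_features <- function(image, roi, d = discretization_spec()) {
  as_feature_class(.glcm_features(discretize(image, roi, d)), "glcm")
}

#' @rdname glcm_features
#' @export
glrlm_features <- function(image, roi, d = discretization_spec()) {
  as_feature_class(.glrlm_features(discretize(image, roi, d)), "glrlm")
}

#' @rdname glcm_features
#' @export
glszm_features <- function(image, roi, d = discretization_spec()) {
  as_feature_class(.glszm_features(discretize(image, roi, d)), "glszm")
}

#' @rdname glcm_features
#' @export
ngtdm_features <- function(image, roi, d = discretization_spec()) {
  as_feature_class(.ngtdm_features(discretize(image, roi, d)), "ngtdm")
}

#' @rdname glcm_features
#' @export
gldm_features <- function(image, roi, d = discretization_spec(), alpha = 0L) {
  as_feature_class(.gldm_features(discretize(image, roi, d), alpha), "gldm")
}
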