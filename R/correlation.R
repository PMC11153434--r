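# Spearman correlation structure between radiomic features, hierarchical
# feature ordering, and a scalar similarity between correlation matrices.

#' Spearman correlation matrix between features
#'
#' Pairwise Spearman correlation over subjects (average ranks for ties).
#' Constant feature columns are flagged and yield undefined (NA) entries.
#'
#' @param table feature table (data.frame with `case`, `method`,
#'   `mask_style` and feature columns), or a plain numeric matrix of
#'   subjects x features.
#' @param method,mask_style optional subset keys applied when `table` is a
#'   feature table.
#' @return a `correlation_matrix`: symmetric matrix with unit diagonal and
#'   attributes `constant` (flagged feature names) and `n_subjects`.
#' @export
spearman_matrix <- function(table, method = NULL, mask_style = NULL) {
  if (is.data.frame(table)) {
    if (!is.null(method)) table <- table[table$method == method, ]
    if (!is.null(mask_style))
      table <- table[table$mask_style == mask_style, ]
    x <- as.matrix(table[, feature_columns(table), drop = FALSE])
  } else {
    x <- as.matrix(table)
  }
  if (nrow(x) < 3L) stop("spearman_matrix: need at least 3 subjects")
  sds <- apply(x, 2, function(v) stats::sd(v[is.finite(v)]))
  constant <- colnames(x)[!is.na(sds) & sds == 0]
  rho <- suppressWarnings(
    stats::cor(x, method = "spearman", use = "pairwise.complete.obs"))
  diag(rho) <- 1
  structure(rho, constant = constant, n_subjects = nrow(x),
            class = c("correlation_matrix", "matrix"))
}

#' Reference feature ordering from a correlation matrix
#'
#' Hierarchical-clustering (average linkage) leaf order on the distance
#' `1 - |rho|`; undefined entries are treated as distance 1. The returned
#' ordering can be reused to render other matrices in the same feature
#' order.
#'
#' @param m a correlation matrix (from [spearman_matrix()]).
#' @return integer permutation of the features, with attribute `labels`.
#' @export
reference_order <- function(m) {
  d <- 1 - abs(unclass(m))
  d[!is.finite(d)] <- 1
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  structure(hc$order, labels = colnames(m)[hc$order])
}

#' Structural similarity between two correlation matrices
#'
#' Pearson correlation of the vectorised upper triangles (undefined entries
#' dropped pairwise); 1 means identical correlation structure.
#'
#' @param m1,m2 correlation matrices over the same feature set.
#' @return scalar similarity in `[-1, 1]`.
#' @export
compare_matrices <- function(m1, m2) {
  m1 <- unclass(m1)
  m2 <- unclass(m2)
  if (!identical(dim(m1), dim(m2)))
    stop("compare_matrices: matrices must share the same feature set")
  v1 <- m1[upper.tri(m1)]
  v2 <- m2[upper.tri(m2)]
  ok <- is.finite(v1) & is.finite(v2)
  if (!any(ok))
    stop("compare_matrices: no overlapping defined entries")
  stats::cor(v1[ok], v2[ok])
}
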