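# Robustness and accuracy assessment: single-measure absolute-agreement
# intraclass correlation under a two-way random-effects model, ICC(2,1),
# with the fixed four-category repeatability scheme.

#' ICC(2,1): two-way random effects, single measure, absolute agreement
#'
#' From the two-way ANOVA decomposition of an n-subjects-by-k-raters matrix,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))` where MSR,
#' MSC and MSE are the between-rows (subjects), between-columns (raters) and
#' residual mean squares.
#'
#' @param m numeric matrix, n subjects x k raters (n >= 2, k >= 2, finite).
#' @return an `icc_result` list: `icc`, `ms_rows`, `ms_cols`, `ms_error`,
#'   `n`, `k`, `category`, `negative_flag`, `valid`.
#' @export
icc_a1 <- function(m) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("icc_a1: all values must be finite")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L) stop("icc_a1: need at least 2 subjects and 2 raters")
  gm <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - gm)^2)
  ss_cols <- n * sum((col_m - gm)^2)
  ss_tot <- sum((m - gm)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (abs(denom) < 1e-300 || ss_tot < 1e-300) {
    # constant matrix (or exactly cancelling components): 0/0, undefined
    return(structure(list(icc = NA_real_, ms_rows = msr, ms_cols = msc,
                          ms_error = mse, n = n, k = k,
                          category = NA_character_, negative_flag = FALSE,
                          valid = FALSE),
                     class = "icc_result"))
  }
  icc <- (msr - mse) / denom
  structure(list(icc = icc, ms_rows = msr, ms_cols = msc, ms_error = mse,
                 n = n, k = k, category = categorize_icc(icc),
                 negative_flag = icc < 0, valid = TRUE),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.4f [%s]%s (n = %d, k = %d)\n", x$icc,
              x$category, if (isTRUE(x$negative_flag)) " (negative)" else "",
              x$n, x$k))
  invisible(x)
}

#' Repeatability category of an ICC value
#'
#' Categories are assigned from the absolute ICC value: excellent
#' (>= 0.9), good (0.75-0.89), moderate (0.5-0.74) or poor (< 0.5).
#'
#' @param icc finite ICC value (vectorised).
#' @return character vector of categories.
#' @export
categorize_icc <- function(icc) {
  a <- abs(icc)
  out <- ifelse(a >= 0.9, "excellent",
                ifelse(a >= 0.75, "good",
                       ifelse(a >= 0.5, "moderate", "poor")))
  out[!is.finite(a)] <- NA_character_
  out
}

#' Comparison design for reliability analysis
#'
#' Three designs over a feature table: `between_masks` compares the two
#' initial-mask styles per segmentation method (k = 2); `among_methods`
#' compares the four individual segmentation methods per mask style
#' (k = 4); `vs_ground_truth` compares each segmentation variant with the
#' ground-truth contour (k = 2, synthetic suites only).
#'
#' @param design one of `"between_masks"`, `"among_methods"`,
#'   `"vs_ground_truth"`.
#' @return a `design_spec` list.
#' @export
design_spec <- function(design = c("between_masks", "among_methods",
                                   "vs_ground_truth")) {
  design <- match.arg(design)
  k <- switch(design, between_masks = 2L, among_methods = 4L,
              vs_ground_truth = 2L)
  structure(list(design = design, k = k), class = "design_spec")
}

feature_columns <- function(table) {
  intersect(feature_catalog()$column, colnames(table))
}

# extract an n x k measurement matrix for one feature under one group
measurement_matrix <- function(table, feature, raters) {
  cases <- sort(unique(table$case))
  m <- matrix(NA_real_, length(cases), length(raters),
              dimnames = list(cases, names(raters)))
  for (j in seq_along(raters)) {
    sel <- raters[[j]]
    sub <- table[table$method == sel$method &
                   table$mask_style == sel$mask_style, , drop = FALSE]
    if (!nrow(sub))
      stop(sprintf("missing rater column: method=%s mask_style=%s",
                   sel$method, sel$mask_style))
    m[match(sub$case, cases), j] <- sub[[feature]]
  }
  m
}

design_groups <- function(spec, methods = c("MASAC", "AP", "ST", "41MAX"),
                          consensus = "ConSeg",
                          mask_styles = c("rectangular", "irregular")) {
  all_methods <- c(methods, consensus)
  switch(spec$design,
    between_masks = {
      g <- lapply(all_methods, function(m) {
        list(group = m,
             raters = lapply(mask_styles, function(s)
               list(method = m, mask_style = s)))
      })
      g
    },
    among_methods = {
      lapply(mask_styles, function(s) {
        list(group = s,
             raters = lapply(methods, function(m)
               list(method = m, mask_style = s)))
      })
    },
    vs_ground_truth = {
      combos <- expand.grid(method = all_methods, mask_style = mask_styles,
                            stringsAsFactors = FALSE)
      lapply(seq_len(nrow(combos)), function(r) {
        list(group = paste(combos$method[r], combos$mask_style[r],
                           sep = "."),
             raters = list(
               list(method = combos$method[r],
                    mask_style = combos$mask_style[r]),
               list(method = "GT", mask_style = "none")))
      })
    })
}

#' Per-feature ICC over a feature table under one comparison design
#'
#' Features invalid (missing) in any cell of a group's measurement matrix
#' are excluded for that group and counted. Negative ICCs are retained in
#' the output with `negative_flag` set; exclusion happens only at the
#' summary stage.
#'
#' @param table feature table (data.frame with `case`, `method`,
#'   `mask_style` and feature columns).
#' @param spec a [design_spec()].
#' @return data.frame with one row per (group, feature): `group`,
#'   `feature`, `icc`, `category`, `negative_flag`, `valid`, plus an
#'   `excluded` attribute counting features dropped per group.
#' @export
run_design <- function(table, spec) {
  feats <- feature_columns(table)
  if (!length(feats)) stop("run_design: no feature columns in table")
  groups <- design_groups(spec)
  rows <- list()
  excluded <- integer()
  for (g in groups) {
    n_excl <- 0L
    for (f in feats) {
      m <- measurement_matrix(table, f, g$raters)
      if (any(is.na(m))) {
        n_excl <- n_excl + 1L
        next
      }
      r <- icc_a1(m)
      rows[[length(rows) + 1]] <-
        data.frame(group = g$group, feature = f, icc = r$icc,
                   category = if (r$valid) r$category else NA_character_,
                   negative_flag = r$negative_flag, valid = r$valid,
                   stringsAsFactors = FALSE)
    }
    excluded[g$group] <- n_excl
  }
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  attr(out, "design") <- spec$design
  out
}

#' Summarize a per-feature ICC table
#'
#' Counts of the four repeatability categories per group (negative and
#' invalid ICCs excluded from the counts, with the excluded fraction
#' reported), the median ICC per group, and the stable-feature set: features
#' with ICC >= `stable_threshold` in every group (and the subset >= 0.9).
#'
#' @param icc_table output of [run_design()] (or several `rbind`-ed ones).
#' @param stable_threshold stability cut-off (default 0.75).
#' @param total_features catalog size used for the stable-set percentage.
#' @return list with `category_counts`, `median_icc`, `negative_fraction`,
#'   `stable_features`, `excellent_features`, `n_stable`, `pct_stable`.
#' @export
summarize_icc <- function(icc_table, stable_threshold = 0.75,
                          total_features = 107L) {
  if (!nrow(icc_table)) stop("summarize_icc: empty ICC table")
  groups <- unique(icc_table$group)
  cats <- c("excellent", "good", "moderate", "poor")
  counts <- matrix(0L, length(groups), 4,
                   dimnames = list(groups, cats))
  med <- numeric(length(groups))
  names(med) <- groups
  neg <- numeric(length(groups))
  names(neg) <- groups
  for (g in groups) {
    sub <- icc_table[icc_table$group == g & icc_table$valid, ]
    keep <- !sub$negative_flag
    counts[g, ] <- vapply(cats, function(cc) sum(sub$category[keep] == cc),
                          0L)
    med[g] <- stats::median(sub$icc)
    neg[g] <- mean(sub$negative_flag)
  }
  # stable features: present, valid and at/above threshold in every group
  feats <- unique(icc_table$feature)
  stable <- character()
  excellent <- character()
  for (f in feats) {
    rows <- icc_table[icc_table$feature == f, ]
    complete <- nrow(rows) == length(groups) && all(rows$valid)
    if (complete) {
      if (all(rows$icc >= stable_threshold)) stable <- c(stable, f)
      if (all(rows$icc >= 0.9)) excellent <- c(excellent, f)
    }
  }
  list(category_counts = counts, median_icc = med, negative_fraction = neg,
       stable_features = stable, excellent_features = excellent,
       n_stable = length(stable),
       pct_stable = 100 * length(stable) / total_features)
}
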