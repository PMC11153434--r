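# Independent brute-force oracles used across the test files. These are
# deliberately naive (nested loops, rle on extracted lattice lines) and
# share no code with the package internals they check.

oracle_dirs <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0), c(1, -1, 0),
  c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1), c(1, 1, 1),
  c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

lab_at <- function(lab, p) {
  d <- dim(lab)
  if (any(p < 1L) || any(p > d)) return(0L)
  lab[p[1], p[2], p[3]]
}

# co-occurrence counts, one voxel pair per (voxel, direction)
oracle_glcm <- function(lab, ng) {
  out <- array(0, c(ng, ng, 13))
  d <- dim(lab)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    li <- lab[x, y, z]
    if (li == 0L) next
    for (k in 1:13) {
      lj <- lab_at(lab, c(x, y, z) + oracle_dirs[k, ])
      if (lj > 0L) out[li, lj, k] <- out[li, lj, k] + 1
    }
  }
  out
}

# run-length counts via rle() on every maximal lattice line per direction
oracle_glrlm <- function(lab, ng) {
  d <- dim(lab)
  maxlen <- max(d)
  out <- array(0, c(ng, maxlen, 13))
  for (k in 1:13) {
    dir <- oracle_dirs[k, ]
    # line starts: voxels whose predecessor is outside the grid
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      prev <- c(x, y, z) - dir
      if (all(prev >= 1L) && all(prev <= d)) next
      # walk the full line, collecting labels
      p <- c(x, y, z)
      seq_lab <- integer()
      while (all(p >= 1L) && all(p <= d)) {
        seq_lab <- c(seq_lab, lab[p[1], p[2], p[3]])
        p <- p + dir
      }
      r <- rle(seq_lab)
      for (j in seq_along(r$values)) {
        v <- r$values[j]
        if (v > 0L)
          out[v, r$lengths[j], k] <- out[v, r$lengths[j], k] + 1
      }
    }
  }
  out
}

# size zones by repeated queue-free region growing
oracle_glszm <- function(lab) {
  d <- dim(lab)
  seen <- array(FALSE, d)
  zones <- NULL
  idx <- which(lab > 0L, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p0 <- idx[r, ]
    if (seen[p0[1], p0[2], p0[3]]) next
    lv <- lab[p0[1], p0[2], p0[3]]
    member <- array(FALSE, d)
    member[p0[1], p0[2], p0[3]] <- TRUE
    repeat {
      grew <- FALSE
      mm <- which(member, arr.ind = TRUE)
      for (q in seq_len(nrow(mm))) {
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
          if (dx == 0 && dy == 0 && dz == 0) next
          p <- mm[q, ] + c(dx, dy, dz)
          if (any(p < 1L) || any(p > d)) next
          if (!member[p[1], p[2], p[3]] && lab[p[1], p[2], p[3]] == lv) {
            member[p[1], p[2], p[3]] <- TRUE
            grew <- TRUE
          }
        }
      }
      if (!grew) break
    }
    seen <- seen | member
    zones <- rbind(zones, c(lv, sum(member)))
  }
  zones
}

oracle_gldm <- function(lab, ng, alpha = 0L) {
  d <- dim(lab)
  out <- matrix(0, ng, 27)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    li <- lab[x, y, z]
    if (li == 0L) next
    dep <- 1L
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      lj <- lab_at(lab, c(x + dx, y + dy, z + dz))
      if (lj > 0L && abs(lj - li) <= alpha) dep <- dep + 1L
    }
    out[li, dep] <- out[li, dep] + 1
  }
  out
}

oracle_ngtdm <- function(lab, ng) {
  d <- dim(lab)
  nvec <- integer(ng)
  svec <- numeric(ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    li <- lab[x, y, z]
    if (li == 0L) next
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      lj <- lab_at(lab, c(x + dx, y + dy, z + dz))
      if (lj > 0L) nb <- c(nb, lj)
    }
    if (length(nb)) {
      nvec[li] <- nvec[li] + 1L
      svec[li] <- svec[li] + abs(li - mean(nb))
    }
  }
  list(n = nvec, s = svec)
}

# two-way random-effects single-measure absolute-agreement ICC computed
# from an aov() decomposition (independent of the package's arithmetic)
oracle_icc_a1 <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  av <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  msr <- av["subj", "Mean Sq"]
  msc <- av["rater", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# small random label volume (labels 1..ng with some background 0)
random_label_volume <- function(dims, ng, p_bg = 0.2) {
  arr <- array(sample(0:ng, prod(dims), replace = TRUE,
                      prob = c(p_bg, rep((1 - p_bg) / ng, ng))), dims)
  storage.mode(arr) <- "integer"
  arr
}

# wrap a numeric array as an image with unit-ish spacing
as_img <- function(arr, spacing = c(1, 1, 1)) {
  image_volume(array(arr, dim(arr)), spacing)
}

full_mask <- function(arr, spacing = c(1, 1, 1)) {
  binary_mask(array(TRUE, dim(arr)), spacing)
}

# compare all five families' features computed through the package against
# features recomputed from independently counted matrices
expect_matches_oracles <- function(lab, spacing = c(1, 1, 1)) {
  dims <- dim(lab)
  # anchor labels at 1 so the image-value round trip through discretize()
  # (bin width 1, ROI-minimum anchored) reproduces them exactly
  pos <- lab > 0L
  lab[pos] <- lab[pos] - min(lab[pos]) + 1L
  ng <- max(lab)
  img <- image_volume(array(as.numeric(lab), dims), spacing)
  roi <- binary_mask(lab > 0L, spacing)
  d <- discretization_spec(bin_width = 1)
  disc <- list(labels = lab, n_levels = ng, bin_width = 1, origin = 1)

  # GLCM: counting oracle, then the same normalization + formulas
  oc <- oracle_glcm(lab, ng)
  per_dir <- list()
  for (k in 1:13) {
    pmat <- oc[, , k] + t(oc[, , k])
    if (sum(pmat) == 0) next
    np <- length(unique(lab[lab > 0L]))
    per_dir[[length(per_dir) + 1]] <-
      conseg:::glcm_features_one(pmat / sum(pmat), np)
  }
  if (length(per_dir)) {
    want <- conseg:::avg_feature_lists(per_dir, conseg:::.catalog$glcm)
    got <- glcm_features(img, roi, d)
    expect_equal(as.numeric(got), as.numeric(unlist(want)),
                 tolerance = 1e-12)
  }

  # GLRLM
  orl <- oracle_glrlm(lab, ng)
  per_dir <- list()
  npx <- sum(lab > 0L)
  for (k in 1:13) {
    m <- matrix(orl[, , k], ng, dim(orl)[2])
    if (sum(m) == 0) next
    per_dir[[length(per_dir) + 1]] <- conseg:::glrlm_features_one(m, npx)
  }
  want <- conseg:::avg_feature_lists(per_dir, conseg:::.catalog$glrlm)
  got <- glrlm_features(img, roi, d)
  expect_equal(as.numeric(got), as.numeric(unlist(want)), tolerance = 1e-12)

  # GLSZM: zone lists must agree exactly (up to order)
  za <- conseg:::cpp_glszm_zones(as.integer(lab), dims)
  zb <- oracle_glszm(lab)
  expect_identical(unname(za[order(za[, 1], za[, 2]), , drop = FALSE]),
                   unname(zb[order(zb[, 1], zb[, 2]), , drop = FALSE]))

  # GLDM
  expect_equal(unname(as.matrix(conseg:::cpp_gldm(as.integer(lab), dims,
                                                  ng, 0L))),
               oracle_gldm(lab, ng, 0L))

  # NGTDM
  nt <- conseg:::cpp_ngtdm(as.integer(lab), dims, ng)
  ot <- oracle_ngtdm(lab, ng)
  expect_identical(as.integer(nt$n), ot$n)
  expect_equal(as.numeric(nt$s), ot$s, tolerance = 1e-12)
}

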