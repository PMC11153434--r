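# Texture matrix features. Count matrices are built in C++ (one pass over
# the cropped ROI); the feature formulas below operate on normalized
# matrices. Gray levels enter the formulas as their bin labels; Ng is the
# number of gray levels present in the ROI.

# ---- GLCM --------------------------------------------------------------

# features of one symmetric, normalized co-occurrence matrix
glcm_features_one <- function(p, ng_present) {
  ng <- nrow(p)
  i <- seq_len(ng)
  px <- rowSums(p)                     # = py by symmetry
  mu <- sum(i * px)
  sig2 <- sum((i - mu)^2 * px)
  ii <- matrix(i, ng, ng)
  jj <- t(ii)
  # diagonal and cross-diagonal probabilities
  kd <- 0:(ng - 1)
  pd <- vapply(kd, function(k) sum(p[abs(ii - jj) == k]), 0)
  ks <- 2:(2 * ng)
  ps <- vapply(ks, function(k) sum(p[(ii + jj) == k]), 0)
  da <- sum(kd * pd)
  hx <- -sum(px * log2(px + .eps))
  hxy <- -sum(p * log2(p + .eps))
  pxpy <- outer(px, px)
  hxy1 <- -sum(p * log2(pxpy + .eps))
  hxy2 <- -sum(pxpy * log2(pxpy + .eps))
  degenerate <- ng_present < 2L || sig2 <= .eps

  mcc <- NA_real_
  if (!degenerate) {
    pres <- which(px > 0)
    q <- matrix(0, length(pres), length(pres))
    for (a in seq_along(pres)) {
      for (b in seq_along(pres)) {
        q[a, b] <- sum(p[pres[a], pres] * p[pres[b], pres] /
                         (px[pres[a]] * px[pres]))
      }
    }
    lam <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- if (length(lam) >= 2) sqrt(max(0, lam[2])) else NA_real_
  }
  list(
    Autocorrelation = sum(p * ii * jj),
    ClusterProminence = sum(p * (ii + jj - 2 * mu)^4),
    ClusterShade = sum(p * (ii + jj - 2 * mu)^3),
    ClusterTendency = sum(p * (ii + jj - 2 * mu)^2),
    Contrast = sum(p * (ii - jj)^2),
    Correlation = if (degenerate) NA_real_
                  else (sum(p * ii * jj) - mu^2) / sig2,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pd * log2(pd + .eps)),
    DifferenceVariance = sum((kd - da)^2 * pd),
    Id = sum(pd / (1 + kd)),
    Idm = sum(pd / (1 + kd^2)),
    Idmn = sum(pd / (1 + kd^2 / ng_present^2)),
    Idn = sum(pd / (1 + kd / ng_present)),
    Imc1 = if (degenerate) NA_real_
           else if (max(hx, hx) <= 0) 0 else (hxy - hxy1) / hx,
    Imc2 = if (degenerate) NA_real_
           else sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy)))),
    InverseVariance = sum(pd[kd > 0] / kd[kd > 0]^2),
    JointAverage = mu,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum(ks * ps),
    SumEntropy = -sum(ps * log2(ps + .eps)),
    SumSquares = sig2)
}

.glcm_features <- function(disc) {
  ng <- disc$n_levels
  counts <- cpp_glcm(as.integer(disc$labels), dim(disc$labels), ng)
  ng_present <- length(unique(disc$labels[disc$labels > 0L]))
  per_dir <- list()
  for (d in 1:13) {
    cmat <- matrix(counts[, , d], ng, ng)
    pmat <- cmat + t(cmat)                 # symmetric co-occurrences
    tot <- sum(pmat)
    if (tot == 0) next
    per_dir[[length(per_dir) + 1]] <- glcm_features_one(pmat / tot,
                                                        ng_present)
  }
  if (!length(per_dir)) {
    out <- as.list(rep(NA_real_, length(.catalog$glcm)))
    names(out) <- .catalog$glcm
    return(out)
  }
  avg_feature_lists(per_dir, .catalog$glcm)
}

# unweighted mean over directions; NA in any direction propagates
avg_feature_lists <- function(lst, nms) {
  out <- lapply(nms, function(nm) {
    mean(vapply(lst, function(l) as.numeric(l[[nm]]), 0))
  })
  names(out) <- nms
  out
}

# ---- GLRLM -------------------------------------------------------------

glrlm_features_one <- function(m, np) {
  nr <- sum(m)
  p <- m / nr
  i <- seq_len(nrow(m))
  l <- seq_len(ncol(m))
  pg <- rowSums(p)
  pl <- colSums(p)
  mu_g <- sum(i * pg)
  mu_l <- sum(l * pl)
  list(
    GrayLevelNonUniformity = sum(rowSums(m)^2) / nr,
    GrayLevelNonUniformityNormalized = sum(pg^2),
    GrayLevelVariance = sum((i - mu_g)^2 * pg),
    HighGrayLevelRunEmphasis = sum(sweep(p, 1, i^2, `*`)),
    LongRunEmphasis = sum(sweep(p, 2, l^2, `*`)),
    LongRunHighGrayLevelEmphasis = sum(outer(i^2, l^2) * p),
    LongRunLowGrayLevelEmphasis = sum(outer(1 / i^2, l^2) * p),
    LowGrayLevelRunEmphasis = sum(sweep(p, 1, 1 / i^2, `*`)),
    RunEntropy = -sum(p * log2(p + .eps)),
    RunLengthNonUniformity = sum(colSums(m)^2) / nr,
    RunLengthNonUniformityNormalized = sum(pl^2),
    RunPercentage = nr / np,
    RunVariance = sum((l - mu_l)^2 * pl),
    ShortRunEmphasis = sum(sweep(p, 2, 1 / l^2, `*`)),
    ShortRunHighGrayLevelEmphasis = sum(outer(i^2, 1 / l^2) * p),
    ShortRunLowGrayLevelEmphasis = sum(outer(1 / i^2, 1 / l^2) * p))
}

.glrlm_features <- function(disc) {
  ng <- disc$n_levels
  counts <- cpp_glrlm(as.integer(disc$labels), dim(disc$labels), ng)
  np <- sum(disc$labels > 0L)
  per_dir <- list()
  for (d in 1:13) {
    m <- matrix(counts[, , d], ng, dim(counts)[2])
    if (sum(m) == 0) next
    per_dir[[length(per_dir) + 1]] <- glrlm_features_one(m, np)
  }
  avg_feature_lists(per_dir, .catalog$glrlm)
}

# ---- GLSZM -------------------------------------------------------------

.glszm_features <- function(disc) {
  zones <- cpp_glszm_zones(as.integer(disc$labels), dim(disc$labels))
  np <- sum(disc$labels > 0L)
  nz <- nrow(zones)
  i <- zones[, 1]    # zone gray level
  s <- zones[, 2]    # zone size
  # per-level and per-size aggregates (each zone has weight 1/nz)
  pg <- tapply(rep(1, nz), i, sum) / nz
  ps <- tapply(rep(1, nz), s, sum) / nz
  gl <- as.numeric(names(pg))
  sl <- as.numeric(names(ps))
  mu_g <- sum(gl * pg)
  mu_s <- sum(sl * ps)
  list(
    GrayLevelNonUniformity = sum((pg * nz)^2) / nz,
    GrayLevelNonUniformityNormalized = sum(pg^2),
    GrayLevelVariance = sum((gl - mu_g)^2 * pg),
    HighGrayLevelZoneEmphasis = sum(i^2) / nz,
    LargeAreaEmphasis = sum(s^2) / nz,
    LargeAreaHighGrayLevelEmphasis = sum(i^2 * s^2) / nz,
    LargeAreaLowGrayLevelEmphasis = sum(s^2 / i^2) / nz,
    LowGrayLevelZoneEmphasis = sum(1 / i^2) / nz,
    SizeZoneNonUniformity = sum((ps * nz)^2) / nz,
    SizeZoneNonUniformityNormalized = sum(ps^2),
    SmallAreaEmphasis = sum(1 / s^2) / nz,
    SmallAreaHighGrayLevelEmphasis = sum(i^2 / s^2) / nz,
    SmallAreaLowGrayLevelEmphasis = sum(1 / (i^2 * s^2)) / nz,
    ZoneEntropy = local({
      pz <- table(paste(i, s)) / nz
      -sum(pz * log2(pz + .eps))
    }),
    ZonePercentage = nz / np,
    ZoneVariance = sum((s - mu_s)^2) / nz)
}

# ---- NGTDM -------------------------------------------------------------

.ngtdm_features <- function(disc) {
  st <- cpp_ngtdm(as.integer(disc$labels), dim(disc$labels), disc$n_levels)
  nvec <- st$n
  svec <- st$s
  nvp <- sum(nvec)
  if (nvp == 0) {
    out <- as.list(rep(NA_real_, 5))
    names(out) <- .catalog$ngtdm
    return(out)
  }
  pres <- which(nvec > 0)
  p <- nvec / nvp
  ngp <- length(pres)
  lv <- pres              # gray levels (labels) present
  pi_ <- p[pres]
  si <- svec[pres]
  ssum <- sum(si)
  # pairwise terms over present levels
  dif2 <- outer(lv, lv, function(a, b) (a - b)^2)
  absd <- outer(lv, lv, function(a, b) abs(a - b))
  contrast <- if (ngp > 1)
    sum(outer(pi_, pi_) * dif2) / (ngp * (ngp - 1)) * (ssum / nvp) else 0
  busy_den <- sum(abs(outer(lv * pi_, lv * pi_, `-`)))
  complexity <- sum(absd * (outer(pi_ * si, rep(1, ngp)) +
                              outer(rep(1, ngp), pi_ * si)) /
                      (outer(pi_, pi_, `+`))) / nvp
  strength <- if (ssum > 0)
    sum(outer(pi_, pi_, `+`) * dif2) / ssum else 0
  list(
    Busyness = if (busy_den > 0) sum(pi_ * si) / busy_den else 0,
    Coarseness = if (sum(pi_ * si) > 0) 1 / sum(pi_ * si) else 1e6,
    Complexity = complexity,
    Contrast = contrast,
    Strength = strength)
}

# ---- GLDM --------------------------------------------------------------

.gldm_features <- function(disc, alpha = 0L) {
  m <- cpp_gldm(as.integer(disc$labels), dim(disc$labels), disc$n_levels,
                as.integer(alpha))
  nz <- sum(m)
  p <- m / nz
  i <- seq_len(nrow(m))
  j <- seq_len(ncol(m))
  pg <- rowSums(p)
  pd <- colSums(p)
  mu_g <- sum(i * pg)
  mu_d <- sum(j * pd)
  list(
    DependenceEntropy = -sum(p * log2(p + .eps)),
    DependenceNonUniformity = sum(colSums(m)^2) / nz,
    DependenceNonUniformityNormalized = sum(pd^2),
    DependenceVariance = sum((j - mu_d)^2 * pd),
    GrayLevelNonUniformity = sum(rowSums(m)^2) / nz,
    GrayLevelVariance = sum((i - mu_g)^2 * pg),
    HighGrayLevelEmphasis = sum(sweep(p, 1, i^2, `*`)),
    LargeDependenceEmphasis = sum(sweep(p, 2, j^2, `*`)),
    LargeDependenceHighGrayLevelEmphasis = sum(outer(i^2, j^2) * p),
    LargeDependenceLowGrayLevelEmphasis = sum(outer(1 / i^2, j^2) * p),
    LowGrayLevelEmphasis = sum(sweep(p, 1, 1 / i^2, `*`)),
    SmallDependenceEmphasis = sum(sweep(p, 2, 1 / j^2, `*`)),
    SmallDependenceHighGrayLevelEmphasis = sum(outer(i^2, 1 / j^2) * p),
    SmallDependenceLowGrayLevelEmphasis = sum(outer(1 / i^2, 1 / j^2) * p))
}
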