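# Shape features: mesh-based volume and surface (marching tetrahedra on the
# binary mask), axis lengths from the eigenvalues of the voxel-centre
# covariance, and maximum diameters from boundary voxel centres.

# boundary voxels: set voxels with at least one 6-neighbour unset
mask_boundary_idx <- function(mask) {
  m <- mask$data
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  interior <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  which(m & !interior, arr.ind = TRUE)
}

max_pairwise_dist <- function(coords) {
  if (nrow(coords) < 2L) return(0)
  max(stats::dist(coords))
}

# mesh the 0.5-isosurface of the (optionally smoothed) mask indicator;
# smoothing sigma is in voxels
mesh_area_volume <- function(mask, smooth_sigma = 0) {
  d <- vol_dims(mask)
  pad <- as.integer(max(1, ceiling(4 * smooth_sigma) + 1))
  dp <- d + 2L * pad
  field <- array(0, dp)
  field[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    mask$data + 0
  if (smooth_sigma > 0)
    field <- cpp_gauss_blur(as.numeric(field), dp, rep(smooth_sigma, 3))
  cpp_mesh_area_volume(as.numeric(field), dp, mask$spacing)
}

.shape_features <- function(mask) {
  sp <- mask$spacing
  d <- vol_dims(mask)
  n <- sum(mask$data)
  av <- mesh_area_volume(mask, smooth_sigma = 0)
  area <- av[1]
  mesh_vol <- av[2]

  idx <- which(mask$data, arr.ind = TRUE)
  coords <- sweep(idx - 1, 2, sp, `*`)
  if (n > 1L) {
    ev <- sort(eigen(stats::cov(coords), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else {
    ev <- c(0, 0, 0)
  }

  bnd <- mask_boundary_idx(mask)
  bcoords <- sweep(bnd - 1, 2, sp, `*`)
  max3d <- max_pairwise_dist(bcoords)
  plane_max <- function(fixed_axis) {
    keep <- setdiff(1:3, fixed_axis)
    mx <- 0
    for (v in unique(bnd[, fixed_axis])) {
      sel <- bnd[, fixed_axis] == v
      mx <- max(mx, max_pairwise_dist(bcoords[sel, keep, drop = FALSE]))
    }
    mx
  }
  list(
    Elongation = sqrt(ev[2] / ev[1]),
    Flatness = sqrt(ev[3] / ev[1]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    MajorAxisLength = 4 * sqrt(ev[1]),
    Maximum2DDiameterColumn = plane_max(1L),  # varying row/slice
    Maximum2DDiameterRow = plane_max(2L),     # varying column/slice
    Maximum2DDiameterSlice = plane_max(3L),   # in-plane
    Maximum3DDiameter = max3d,
    MeshVolume = mesh_vol,
    MinorAxisLength = 4 * sqrt(ev[2]),
    Sphericity = (36 * pi * mesh_vol^2)^(1 / 3) / area,
    SurfaceArea = area,
    SurfaceVolumeRatio = area / mesh_vol,
    VoxelVolume = n * prod(sp))
}
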