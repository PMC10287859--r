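# First-order (histogram) and shape descriptors.

firstorder_names <- c("Energy", "TotalEnergy", "Entropy", "Minimum",
  "Percentile10", "Percentile90", "Maximum", "Mean", "Median",
  "InterquartileRange", "Range", "MeanAbsoluteDeviation",
  "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness", "Kurtosis",
  "Variance", "Uniformity")

# x: in-mask intensities; lv: in-mask discretized gray levels (same order);
# voxel_mm3: physical voxel volume. Moments use population (1/n) denominators;
# Kurtosis is not excess-corrected.
firstorder_features <- function(x, lv, voxel_mm3) {
  n <- length(x)
  p <- tabulate(lv) / n
  p <- p[p > 0]
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  rob <- x[x >= q[1] & x <= q[4]]
  out <- c(
    Energy = sum(x^2),
    TotalEnergy = voxel_mm3 * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    Percentile10 = q[1],
    Percentile90 = q[4],
    Maximum = max(x),
    Mean = mu,
    Median = stats::median(x),
    InterquartileRange = q[3] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(rob - mean(rob))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mean((x - mu)^4) / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2)
  )
  out[firstorder_names]
}

shape_names <- c("MeshVolume", "VoxelVolume", "SurfaceArea",
  "SurfaceVolumeRatio", "Sphericity", "MajorAxisLength", "MinorAxisLength",
  "LeastAxisLength", "Elongation", "Flatness", "Maximum3DDiameter",
  "Maximum2DDiameterSlice", "Maximum2DDiameterColumn", "Maximum2DDiameterRow")

# voxel-based shape descriptors on the (isotropic) resampled grid; surface is
# the voxel surface (exposed faces), volume the voxel volume. These are
# documented approximations of mesh-based IBSI definitions.
shape_features <- function(maskvals, spacing) {
  dm <- dim(maskvals)
  m <- maskvals != 0
  nvox <- sum(m)
  vv <- prod(spacing)
  vol <- nvox * vv
  # exposed faces per axis
  area <- 0
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3], spacing[1] * spacing[2])
  for (a in 1:3) {
    sh_p <- .shift_mask_zero(m, a, 1L); sh_m <- .shift_mask_zero(m, a, -1L)
    area <- area + (sum(m & !sh_p) + sum(m & !sh_m)) * face_area[a]
  }
  coords <- which(m, arr.ind = TRUE)
  pc <- sweep(coords, 2, rep(1, 3)) * rep(spacing, each = nrow(coords))
  # principal axis lengths from the coordinate covariance (population)
  if (nrow(pc) > 1) {
    cv <- stats::cov(pc) * (nrow(pc) - 1) / nrow(pc)
    ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else ev <- c(0, 0, 0)
  axes <- 4 * sqrt(ev)
  # boundary voxels suffice for diameters
  interior <- m
  for (a in 1:3) interior <- interior & .shift_mask_zero(m, a, 1L) & .shift_mask_zero(m, a, -1L)
  bnd <- which(m & !interior, arr.ind = TRUE)
  if (nrow(bnd) == 0) bnd <- coords
  bp <- sweep(bnd, 2, rep(1, 3)) * rep(spacing, each = nrow(bnd))
  d3 <- .max_pairwise_dist(bp)
  d_slice <- .max_grouped_dist(bp, group_axis = 3L)   # within fixed z: x-y plane
  d_col <- .max_grouped_dist(bp, group_axis = 2L)     # fixed y: x-z plane
  d_row <- .max_grouped_dist(bp, group_axis = 1L)     # fixed x: y-z plane
  sph <- if (area > 0) (36 * pi * vol^2)^(1 / 3) / area else NaN
  c(MeshVolume = vol, VoxelVolume = vol, SurfaceArea = area,
    SurfaceVolumeRatio = if (vol > 0) area / vol else NaN,
    Sphericity = sph,
    MajorAxisLength = axes[1], MinorAxisLength = axes[2],
    LeastAxisLength = axes[3],
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NaN,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else NaN,
    Maximum3DDiameter = d3,
    Maximum2DDiameterSlice = d_slice,
    Maximum2DDiameterColumn = d_col,
    Maximum2DDiameterRow = d_row)[shape_names]
}

.shift_mask_zero <- function(m, axis, by) {
  dm <- dim(m)
  out <- array(FALSE, dim = dm)
  tx <- max(1L, 1L + (axis == 1L) * by):min(dm[1], dm[1] + (axis == 1L) * by)
  ty <- max(1L, 1L + (axis == 2L) * by):min(dm[2], dm[2] + (axis == 2L) * by)
  tz <- max(1L, 1L + (axis == 3L) * by):min(dm[3], dm[3] + (axis == 3L) * by)
  out[tx, ty, tz] <- m[tx - (axis == 1L) * by, ty - (axis == 2L) * by,
                       tz - (axis == 3L) * by]
  out
}

.max_pairwise_dist <- function(p) {
  if (nrow(p) < 2) return(0)
  if (nrow(p) > 3000) {  # thin dense clouds via their bounding shell
    keep <- unique(c(seq(1, nrow(p), length.out = 3000)))
    p <- p[round(keep), , drop = FALSE]
  }
  max(stats::dist(p))
}

.max_grouped_dist <- function(p, group_axis) {
  plane <- setdiff(1:3, group_axis)
  groups <- split(seq_len(nrow(p)), p[, group_axis])
  best <- 0
  for (g in groups) {
    if (length(g) < 2) next
    best <- max(best, .max_pairwise_dist(p[g, plane, drop = FALSE]))
  }
  best
}
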