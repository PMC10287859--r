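# Physical-unit binary morphology and isotropic resampling.
#
# The peritumoral compartment ("tissue surrounding tumor", TST) is the set
# difference between a 2-mm dilation and a 2-mm erosion of the tumor mask: a
# ring straddling the boundary, 4 mm thick in physical units regardless of the
# voxel grid. All structuring elements are discrete balls in millimetres.

#' Discrete ball structuring element in physical units
#'
#' Enumerates all integer voxel offsets whose physical distance from the
#' centre, under the given per-axis spacing, is at most `radius_mm`. The set is
#' symmetric under axis reflection, so it serves both dilation and erosion.
#'
#' @param radius_mm ball radius in mm (>= 0).
#' @param spacing_mm numeric length-3 voxel spacing in mm.
#' @return integer matrix with 3 columns (dx, dy, dz), one row per offset.
#' @examples
#' nrow(ball_element(2, c(1, 1, 1)))  # 33 offsets
#' @export
ball_element <- function(radius_mm, spacing_mm) {
  if (!is.finite(radius_mm) || radius_mm < 0) stop("`radius_mm` must be >= 0")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) stop("`spacing_mm` must be 3 positive numbers")
  rv <- floor(radius_mm / spacing_mm + 1e-9)
  g <- expand.grid(dx = -rv[1]:rv[1], dy = -rv[2]:rv[2], dz = -rv[3]:rv[3])
  d2 <- (g$dx * spacing_mm[1])^2 + (g$dy * spacing_mm[2])^2 + (g$dz * spacing_mm[3])^2
  keep <- d2 <= radius_mm^2 * (1 + 1e-9) + 1e-12
  as.matrix(g[keep, , drop = FALSE])
}

# shift-and-combine engine: OR for dilation, AND for erosion.
# Outside the grid counts as background, so erosion eats inward at the borders
# (equivalently: erode(m) == !dilate(!m) on a padded grid).
.shift_combine <- function(vals, offsets, op = c("or", "and")) {
  op <- match.arg(op)
  dm <- dim(vals)
  out <- array(op == "and", dim = dm)
  lv <- vals != 0
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    tx <- max(1L, 1L + o[1]):min(dm[1], dm[1] + o[1])
    ty <- max(1L, 1L + o[2]):min(dm[2], dm[2] + o[2])
    tz <- max(1L, 1L + o[3]):min(dm[3], dm[3] + o[3])
    shifted <- array(FALSE, dim = dm)
    shifted[tx, ty, tz] <- lv[tx - o[1], ty - o[2], tz - o[3]]
    out <- if (op == "or") out | shifted else out & shifted
  }
  out
}

#' Morphological dilation of a mask by a physical radius
#' @param mask a [binary_mask()].
#' @param radius_mm dilation radius in mm.
#' @return dilated `binary_mask`.
#' @export
dilate_mask <- function(mask, radius_mm) {
  stopifnot(inherits(mask, "binary_mask"))
  el <- ball_element(radius_mm, mask$spacing_mm)
  binary_mask(.shift_combine(mask$values, el, "or"), mask$spacing_mm, mask$origin_mm)
}

#' Morphological erosion of a mask by a physical radius
#' @inheritParams dilate_mask
#' @param radius_mm erosion radius in mm.
#' @return eroded `binary_mask` (voxels outside the grid count as background).
#' @export
erode_mask <- function(mask, radius_mm) {
  stopifnot(inherits(mask, "binary_mask"))
  el <- ball_element(radius_mm, mask$spacing_mm)
  binary_mask(.shift_combine(mask$values, el, "and"), mask$spacing_mm, mask$origin_mm)
}

#' Build the peritumoral ring mask (TST)
#'
#' Dilates the tumor mask by `dilate_mm`, erodes it by `erode_mm`, and
#' subtracts: `TST = dilate(mask) AND NOT erode(mask)`. With the 2 mm defaults
#' the ring is 4 mm thick and straddles the tumor boundary, capturing the
#' outermost tumor rim plus the immediately surrounding tissue.
#'
#' @param mask tumor `binary_mask` (nonempty).
#' @param dilate_mm,erode_mm radii in mm (defaults 2 and 2).
#' @return ring `binary_mask`.
#' @export
build_tst <- function(mask, dilate_mm = 2, erode_mm = 2) {
  stopifnot(inherits(mask, "binary_mask"))
  if (sum(mask$values) == 0) stop("tumor mask is empty; cannot build TST")
  d <- dilate_mask(mask, dilate_mm)
  e <- erode_mask(mask, erode_mm)
  ring <- d$values & !e$values
  if (!any(ring)) stop("TST ring is empty (dilate_mm = ", dilate_mm,
                       ", erode_mm = ", erode_mm, ")")
  binary_mask(ring, mask$spacing_mm, mask$origin_mm)
}

#' QC summary for a ring mask
#'
#' Automatic stand-in for visual inspection of the ring: reports voxel count,
#' physical volume, and whether the ring touches the image boundary (where the
#' dilation was clipped). The ring is not clipped to any anatomy mask.
#'
#' @param ring a `binary_mask` as returned by [build_tst()].
#' @return list with `n_voxels`, `volume_mm3`, `touches_boundary`.
#' @export
tst_qc <- function(ring) {
  stopifnot(inherits(ring, "binary_mask"))
  v <- ring$values
  dm <- dim(v)
  touches <- any(v[1, , ] != 0) || any(v[dm[1], , ] != 0) ||
    any(v[, 1, ] != 0) || any(v[, dm[2], ] != 0) ||
    any(v[, , 1] != 0) || any(v[, , dm[3]] != 0)
  list(n_voxels = sum(v), volume_mm3 = sum(v) * prod(ring$spacing_mm),
       touches_boundary = touches)
}

# --- resampling ---------------------------------------------------------------

# fractional 0-based voxel coordinates of the output grid in the input grid
.resample_coords <- function(dm_in, spacing_in, target_mm) {
  n_out <- pmax(1L, as.integer(floor((dm_in - 1) * spacing_in / target_mm + 1e-9)) + 1L)
  coords <- lapply(1:3, function(a) (seq_len(n_out[a]) - 1) * target_mm / spacing_in[a])
  list(n_out = n_out, coords = coords)
}

.interp_trilinear <- function(vals, cx, cy, cz) {
  dm <- dim(vals)
  i0 <- pmin(pmax(floor(cx), 0), max(dm[1] - 2, 0)); wx <- pmin(pmax(cx - i0, 0), 1)
  j0 <- pmin(pmax(floor(cy), 0), max(dm[2] - 2, 0)); wy <- pmin(pmax(cy - j0, 0), 1)
  k0 <- pmin(pmax(floor(cz), 0), max(dm[3] - 2, 0)); wz <- pmin(pmax(cz - k0, 0), 1)
  nx <- length(cx); ny <- length(cy); nz <- length(cz)
  I0 <- rep(i0 + 1, times = ny * nz); WX <- rep(wx, times = ny * nz)
  J0 <- rep(rep(j0 + 1, each = nx), times = nz); WY <- rep(rep(wy, each = nx), times = nz)
  K0 <- rep(k0 + 1, each = nx * ny); WZ <- rep(wz, each = nx * ny)
  sx <- dm[1]; sxy <- dm[1] * dm[2]
  base <- I0 + (J0 - 1) * sx + (K0 - 1) * sxy
  ix <- if (dm[1] > 1) 1L else 0L
  iy <- if (dm[2] > 1) sx else 0L
  iz <- if (dm[3] > 1) sxy else 0L
  out <- vals[base] * (1 - WX) * (1 - WY) * (1 - WZ) +
    vals[base + ix] * WX * (1 - WY) * (1 - WZ) +
    vals[base + iy] * (1 - WX) * WY * (1 - WZ) +
    vals[base + ix + iy] * WX * WY * (1 - WZ) +
    vals[base + iz] * (1 - WX) * (1 - WY) * WZ +
    vals[base + ix + iz] * WX * (1 - WY) * WZ +
    vals[base + iy + iz] * (1 - WX) * WY * WZ +
    vals[base + ix + iy + iz] * WX * WY * WZ
  array(out, dim = c(nx, ny, nz))
}

.interp_nearest <- function(vals, cx, cy, cz) {
  dm <- dim(vals)
  i <- pmin(pmax(round(cx) + 1, 1), dm[1])
  j <- pmin(pmax(round(cy) + 1, 1), dm[2])
  k <- pmin(pmax(round(cz) + 1, 1), dm[3])
  nx <- length(cx); ny <- length(cy); nz <- length(cz)
  idx <- rep(i, times = ny * nz) +
    (rep(rep(j, each = nx), times = nz) - 1) * dm[1] +
    (rep(k, each = nx * ny) - 1) * dm[1] * dm[2]
  array(vals[idx], dim = c(nx, ny, nz))
}

.resample_volume <- function(volume, target_mm) {
  if (max(abs(volume$spacing_mm - target_mm)) < 1e-9) return(volume)  # identity fast path
  rc <- .resample_coords(dim(volume$values), volume$spacing_mm, target_mm)
  out <- .interp_trilinear(volume$values, rc$coords[[1]], rc$coords[[2]], rc$coords[[3]])
  mri_volume(out, rep(target_mm, 3), volume$origin_mm)
}

.resample_mask <- function(mask, target_mm) {
  if (max(abs(mask$spacing_mm - target_mm)) < 1e-9) return(mask)
  rc <- .resample_coords(dim(mask$values), mask$spacing_mm, target_mm)
  out <- .interp_nearest(mask$values, rc$coords[[1]], rc$coords[[2]], rc$coords[[3]])
  binary_mask(out != 0, rep(target_mm, 3), mask$origin_mm)
}

#' Resample a volume/mask pair to an isotropic grid
#'
#' The image is interpolated trilinearly, the mask with nearest-neighbour
#' lookup (then re-binarised). The output grid starts at the same first-voxel
#' centre and spans the physical extent of the input within one voxel.
#'
#' @param volume an [mri_volume()].
#' @param mask a [binary_mask()] on the same grid.
#' @param target_mm isotropic target spacing in mm (> 0).
#' @return list with elements `volume` and `mask` on the new grid.
#' @export
resample_isotropic <- function(volume, mask, target_mm) {
  stopifnot(inherits(volume, "mri_volume"), inherits(mask, "binary_mask"))
  if (!is.finite(target_mm) || target_mm <= 0) stop("`target_mm` must be > 0")
  check_same_grid(volume, mask)
  v <- .resample_volume(volume, target_mm)
  m <- .resample_mask(mask, target_mm)
  if (sum(m$values) == 0)
    stop("mask is empty after resampling to ", target_mm,
         " mm; feature extraction impossible")
  list(volume = v, mask = m)
}
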