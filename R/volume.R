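#' 3D image volume with physical geometry
#'
#' A volume couples a 3D numeric array with its voxel spacing (mm) and the
#' physical coordinates of the first voxel centre. All geometric operations in
#' the package (structuring elements, ring construction, resampling) work in
#' millimetres, so anisotropic grids behave correctly.
#'
#' @param values 3D numeric array of voxel intensities (finite).
#' @param spacing_mm numeric length-3, voxel size along each axis in mm (> 0).
#' @param origin_mm numeric length-3, physical position of voxel (1,1,1) centre.
#' @return An object of class `mri_volume`.
#' @export
mri_volume <- function(values, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array, got ", length(dim(values)), " dims")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive finite numbers")
  if (any(!is.finite(values)))
    stop("volume values must all be finite")
  structure(
    list(values = values, spacing_mm = spacing_mm, origin_mm = as.numeric(origin_mm)),
    class = "mri_volume"
  )
}

#' Binary mask on a voxel grid
#'
#' Same grid metadata as [mri_volume()] with values restricted to {0, 1}.
#' A mask paired with a volume must share `dim`, `spacing_mm` and `origin_mm`
#' exactly.
#'
#' @param values 3D array coercible to 0/1 (logical or numeric).
#' @inheritParams mri_volume
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  v <- array(as.integer(values != 0), dim = dim(values))
  if (any(is.na(values)))
    stop("mask values must not contain NA")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive finite numbers")
  structure(
    list(values = v, spacing_mm = spacing_mm, origin_mm = as.numeric(origin_mm)),
    class = "binary_mask"
  )
}

#' @export
print.mri_volume <- function(x, ...) {
  cat("<mri_volume>", paste(dim(x$values), collapse = "x"),
      "voxels, spacing", paste(format(x$spacing_mm), collapse = "x"), "mm\n")
  cat("  intensity range:", paste(format(range(x$values)), collapse = " .. "), "\n")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask>", paste(dim(x$values), collapse = "x"),
      "voxels, spacing", paste(format(x$spacing_mm), collapse = "x"), "mm,",
      sum(x$values), "foreground voxels\n")
  invisible(x)
}

#' Number of foreground voxels in a mask
#' @param mask a `binary_mask`.
#' @return integer count.
#' @export
mask_voxel_count <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$values)
}

#' Dice overlap between two masks
#' @param a,b `binary_mask` objects on the same grid.
#' @return Dice coefficient in [0, 1]; NA if both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  check_same_grid(a, b)
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0) return(NA_real_)
  2 * sum(a$values & b$values) / (na + nb)
}

# grid compatibility check shared by paired-volume operations
check_same_grid <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("grid mismatch: dims ", paste(dim(a$values), collapse = "x"), " vs ",
         paste(dim(b$values), collapse = "x"))
  if (max(abs(a$spacing_mm - b$spacing_mm)) > 1e-9)
    stop("grid mismatch: spacing differs")
  if (max(abs(a$origin_mm - b$origin_mm)) > 1e-6)
    stop("grid mismatch: origin differs")
  invisible(TRUE)
}

#' Voxel volume in cubic millimetres
#' @param x an `mri_volume` or `binary_mask`.
#' @return scalar mm^3 per voxel.
#' @export
voxel_volume_mm3 <- function(x) prod(x$spacing_mm)
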