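# Minimal NIfTI-1 I/O.
#
# Only what the pipeline needs: single-file .nii(.gz), 3D, datatypes uint8 /
# int16 / int32 / float32 / float64, spacing from pixdim, origin from qoffset_*
# (axis-aligned; rotation quaternions are not interpreted). Written files carry
# qform_code = 1 with an identity orientation.

NIFTI_HDR_SIZE <- 348L
NIFTI_VOX_OFFSET <- 352

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param as_mask logical; return a [binary_mask()] (values binarised at != 0)
#'   instead of an [mri_volume()].
#' @return `mri_volume` or `binary_mask`.
#' @details Supports 3D single-file NIfTI-1 with scalar datatypes. Orientation
#' quaternions/affines are ignored: voxel axes are taken as physical axes, with
#' spacing from `pixdim[2:4]` and origin from `qoffset_{x,y,z}`.
#' @export
read_nifti <- function(path, as_mask = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1, size = 4, endian = "little")
  endian <- "little"
  if (sizeof_hdr != NIFTI_HDR_SIZE) {
    # try big endian
    sw <- .swap_int32(sizeof_hdr)
    if (sw == NIFTI_HDR_SIZE) endian <- "big"
    else stop("not a NIfTI-1 file (sizeof_hdr = ", sizeof_hdr, "): ", path)
  }
  readBin(con, "raw", 36)                                   # unused fields
  dims <- readBin(con, "integer", 8, size = 2, endian = endian)
  readBin(con, "raw", 14)                                   # intent fields
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  readBin(con, "integer", 1, size = 2, endian = endian)     # bitpix
  readBin(con, "integer", 1, size = 2, endian = endian)     # slice_start
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "numeric", 1, size = 4, endian = endian)
  readBin(con, "raw", 224)                                  # through intent_name
  magic <- rawToChar(readBin(con, "raw", 4), multiple = FALSE)
  if (!grepl("^n\\+1", magic)) stop("unsupported NIfTI magic: ", magic)
  # re-read header bytes to pick out qoffset (gz connections cannot seek)
  con2 <- gzfile(path, "rb")
  hdr <- readBin(con2, "raw", NIFTI_HDR_SIZE)
  close(con2)
  qoffset <- readBin(hdr[269:280], "numeric", 3, size = 4, endian = endian)

  ndim <- dims[1]
  if (ndim < 3) stop("expected a 3D NIfTI volume, got ndim = ", ndim)
  nx <- dims[2]; ny <- dims[3]; nz <- dims[4]
  if (ndim > 3 && any(dims[5:(1 + ndim)] > 1))
    stop("only 3D volumes are supported")
  n <- as.numeric(nx) * ny * nz
  spec <- switch(as.character(datatype),
    "2"  = list(what = "integer", size = 1, signed = FALSE),
    "4"  = list(what = "integer", size = 2, signed = TRUE),
    "8"  = list(what = "integer", size = 4, signed = TRUE),
    "16" = list(what = "numeric", size = 4, signed = TRUE),
    "64" = list(what = "numeric", size = 8, signed = TRUE),
    stop("unsupported NIfTI datatype code: ", datatype))
  # skip any extension bytes between header and voxel data
  to_skip <- round(vox_offset) - NIFTI_HDR_SIZE
  if (to_skip > 0) readBin(con, "raw", to_skip)
  vals <- readBin(con, spec$what, n, size = spec$size, signed = spec$signed,
                  endian = endian)
  if (length(vals) != n) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  arr <- array(as.numeric(vals), dim = c(nx, ny, nz))
  spacing <- abs(pixdim[2:4])
  spacing[spacing == 0] <- 1
  if (as_mask) binary_mask(arr, spacing, qoffset)
  else mri_volume(arr, spacing, qoffset)
}

#' Write a volume or mask as NIfTI-1
#'
#' @param x an `mri_volume` (written as float32) or `binary_mask` (uint8).
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  is_mask <- inherits(x, "binary_mask")
  if (!is_mask && !inherits(x, "mri_volume"))
    stop("`x` must be an mri_volume or binary_mask")
  dm <- dim(x$values)
  datatype <- if (is_mask) 2L else 16L
  bitpix <- if (is_mask) 8L else 32L
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(NIFTI_HDR_SIZE, con, size = 4, endian = "little")
  writeBin(raw(36), con)
  writeBin(as.integer(c(3L, dm, 1L, 1L, 1L, 1L)), con, size = 2, endian = "little")
  writeBin(raw(14), con)
  writeBin(as.integer(c(datatype, bitpix, 0L)), con, size = 2, endian = "little")
  writeBin(c(1, x$spacing_mm, 0, 0, 0, 0), con, size = 4, endian = "little")
  writeBin(NIFTI_VOX_OFFSET, con, size = 4, endian = "little")  # vox_offset
  writeBin(c(1, 0), con, size = 4, endian = "little")           # scl_slope/inter
  writeBin(raw(4), con)                                         # slice_end/code, xyzt_units
  writeBin(c(0, 0, 0), con, size = 4, endian = "little")        # cal_max, cal_min, slice_duration
  writeBin(0, con, size = 4, endian = "little")                 # toffset
  writeBin(c(0L, 0L), con, size = 4, endian = "little")         # glmax, glmin
  writeBin(raw(104), con)                                       # descrip + aux_file
  writeBin(as.integer(c(1L, 0L)), con, size = 2, endian = "little")  # qform, sform codes
  writeBin(c(0, 0, 0), con, size = 4, endian = "little")        # quatern b,c,d (identity)
  writeBin(as.numeric(x$origin_mm), con, size = 4, endian = "little")
  writeBin(numeric(12), con, size = 4, endian = "little")       # srow_x/y/z
  writeBin(raw(16), con)                                        # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con)        # magic
  writeBin(raw(4), con)                                         # extension flag
  if (is_mask) {
    writeBin(as.raw(as.integer(x$values)), con)
  } else {
    writeBin(as.numeric(x$values), con, size = 4, endian = "little")
  }
  invisible(path)
}

.swap_int32 <- function(x) {
  b <- writeBin(as.integer(x), raw(), size = 4, endian = "little")
  readBin(rev(b), "integer", 1, size = 4, endian = "little")
}
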