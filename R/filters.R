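# Image filters applied before feature extraction.
#
# Each filter maps the (resampled, cropped) intensity array to one or more
# derived images; intensity features are then computed on every derived image
# within the mask. Definitions follow the conventions of widely used IBSI-style
# extractors; bit-for-bit parity with any particular implementation is a
# non-goal. Range-preserving rescaling constants (square, squareroot,
# logarithm, exponential) keep the fixed 25-unit bin width meaningful across
# derived images.

.shift_arr <- function(x, axis, by) {
  # shift with edge replication
  dm <- dim(x)
  idx <- pmin(pmax(seq_len(dm[axis]) + by, 1L), dm[axis])
  if (axis == 1L) x[idx, , , drop = FALSE]
  else if (axis == 2L) x[, idx, , drop = FALSE]
  else x[, , idx, drop = FALSE]
}

# single-level undecimated Haar decomposition along one axis
.haar_axis <- function(x, axis, kind) {
  nb <- .shift_arr(x, axis, 1L)
  if (kind == "L") (x + nb) / 2 else (x - nb) / 2
}

.wavelet_bands <- function(x) {
  out <- list()
  for (bx in c("L", "H")) {
    fx <- .haar_axis(x, 1L, bx)
    for (by in c("L", "H")) {
      fy <- .haar_axis(fx, 2L, by)
      for (bz in c("L", "H")) {
        out[[paste0("wavelet-", bx, by, bz)]] <- .haar_axis(fy, 3L, bz)
      }
    }
  }
  out
}

.filter_square <- function(x) {
  mx <- max(abs(x))
  if (mx == 0) return(x)
  (x / sqrt(mx))^2
}

.filter_squareroot <- function(x) {
  mx <- max(abs(x))
  if (mx == 0) return(x)
  sign(x) * sqrt(abs(x) * mx)
}

.filter_logarithm <- function(x) {
  mx <- max(abs(x))
  if (mx == 0) return(x)
  sign(x) * log(abs(x) + 1) * mx / log(mx + 1)
}

.filter_exponential <- function(x) {
  mx <- max(abs(x))
  if (mx == 0) return(exp(x))
  exp(x * log(mx) / mx)
}

.filter_gradient <- function(x, spacing) {
  g2 <- array(0, dim = dim(x))
  for (a in 1:3) {
    if (dim(x)[a] < 2) next
    d <- (.shift_arr(x, a, 1L) - .shift_arr(x, a, -1L)) / (2 * spacing[a])
    g2 <- g2 + d^2
  }
  sqrt(g2)
}

# rotation-invariant uniform 2D local binary pattern (P = 8, R = 1), slice-wise
.filter_lbp2d <- function(x) {
  dm <- dim(x)
  code <- array(0L, dim = dm)
  trans <- array(0L, dim = dm)
  offs <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1), c(0, -1), c(1, -1))
  bits <- vector("list", 8L)
  for (k in 1:8) {
    nb <- .shift_arr(.shift_arr(x, 1L, offs[[k]][1]), 2L, offs[[k]][2])
    bits[[k]] <- (nb >= x)
  }
  nset <- Reduce(`+`, bits)
  for (k in 1:8) {
    nxt <- bits[[if (k == 8) 1 else k + 1]]
    trans <- trans + (bits[[k]] != nxt)
  }
  # uniform patterns (<= 2 transitions) -> number of set bits; otherwise 9
  out <- ifelse(trans <= 2L, nset, 9L)
  array(as.numeric(out), dim = dm)
}

.gauss_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

.smooth_axis <- function(x, axis, kernel) {
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, dim = dim(x))
  for (i in seq_along(kernel)) out <- out + kernel[i] * .shift_arr(x, axis, i - r - 1L)
  out
}

.filter_log_of_gaussian <- function(x, spacing, sigma_mm) {
  s <- x
  for (a in 1:3) {
    sv <- sigma_mm / spacing[a]
    if (dim(x)[a] >= 3) s <- .smooth_axis(s, a, .gauss_kernel(sv))
  }
  lap <- array(0, dim = dim(x))
  for (a in 1:3) {
    if (dim(x)[a] < 3) next
    lap <- lap + (.shift_arr(s, a, 1L) - 2 * s + .shift_arr(s, a, -1L)) / spacing[a]^2
  }
  sigma_mm^2 * lap
}

# Expand a filter list into named derived images. LoG contributes one image per
# sigma; lbp3d is accepted in configs but only as a no-op placeholder.
derive_images <- function(values, spacing, filters, log_sigma_mm = numeric(0)) {
  out <- list()
  for (f in filters) {
    switch(f,
      original = { out[["original"]] <- values },
      wavelet = { out <- c(out, .wavelet_bands(values)) },
      square = { out[["square"]] <- .filter_square(values) },
      squareroot = { out[["squareroot"]] <- .filter_squareroot(values) },
      logarithm = { out[["logarithm"]] <- .filter_logarithm(values) },
      exponential = { out[["exponential"]] <- .filter_exponential(values) },
      gradient = { out[["gradient"]] <- .filter_gradient(values, spacing) },
      lbp2d = { out[["lbp2d"]] <- .filter_lbp2d(values) },
      log_of_gaussian = {
        for (s in log_sigma_mm)
          out[[sprintf("log-sigma-%g-mm", s)]] <-
            .filter_log_of_gaussian(values, spacing, s)
      },
      lbp3d = {
        # contributes no derived image by default (see extraction_config)
      },
      stop("unknown filter: ", f)
    )
  }
  out
}
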