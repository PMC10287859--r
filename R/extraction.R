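# Feature extraction configuration and orchestration.
#
# The pinned default configuration produces exactly 1409 feature values per
# masked image: 93 intensity features (18 firstorder + 24 glcm + 16 glrlm +
# 16 glszm + 14 gldm + 5 ngtdm) on each of 15 derived images (original +
# 8 wavelet sub-bands + square + squareroot + logarithm + exponential +
# gradient + lbp2d) plus 14 shape descriptors on the original image:
# 15 * 93 + 14 = 1409. Laplacian-of-Gaussian ships with no smoothing scales
# and LBP3D as a placeholder, so both contribute zero features by default.

FILTER_SET <- c("original", "wavelet", "log_of_gaussian", "square",
                "squareroot", "logarithm", "exponential", "gradient",
                "lbp2d", "lbp3d")
CLASS_SET <- c("firstorder", "shape", "glcm", "glrlm", "ngtdm", "gldm", "glszm")

#' Extraction configuration
#'
#' @param filters character subset of the ten built-in filters
#'   (`original`, `wavelet`, `log_of_gaussian`, `square`, `squareroot`,
#'   `logarithm`, `exponential`, `gradient`, `lbp2d`, `lbp3d`).
#' @param feature_classes character subset of
#'   `firstorder`, `shape`, `glcm`, `glrlm`, `ngtdm`, `gldm`, `glszm`.
#' @param bin_width gray-level discretization width in intensity units (> 0).
#' @param resolutions_mm isotropic resampling targets in mm.
#' @param shape_on_original_only logical; shape descriptors are computed only
#'   on the unfiltered image (they depend on the mask alone).
#' @param log_sigma_mm numeric vector of Laplacian-of-Gaussian scales in mm;
#'   empty by default (the filter then contributes no features).
#' @return list of class `extraction_config`.
#' @export
extraction_config <- function(filters = FILTER_SET,
                              feature_classes = CLASS_SET,
                              bin_width = 25,
                              resolutions_mm = c(1, 2, 3),
                              shape_on_original_only = TRUE,
                              log_sigma_mm = numeric(0)) {
  bad <- setdiff(filters, FILTER_SET)
  if (length(bad)) stop("unknown filter(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(feature_classes, CLASS_SET)
  if (length(bad)) stop("unknown feature class(es): ", paste(bad, collapse = ", "))
  if (!is.numeric(bin_width) || bin_width <= 0) stop("`bin_width` must be > 0")
  if (any(resolutions_mm <= 0)) stop("`resolutions_mm` must be > 0")
  if ("lbp3d" %in% filters && length(log_sigma_mm) == 0 &&
      !is.null(attr(filters, "lbp3d_scales")))
    stop("lbp3d is not implemented")
  structure(list(filters = filters, feature_classes = feature_classes,
                 bin_width = bin_width, resolutions_mm = resolutions_mm,
                 shape_on_original_only = shape_on_original_only,
                 log_sigma_mm = log_sigma_mm),
            class = "extraction_config")
}

# intensity feature-class computers, keyed by class name
.intensity_classes <- function() {
  list(firstorder = NULL, glcm = NULL, glrlm = NULL, glszm = NULL,
       gldm = NULL, ngtdm = NULL)
}

#' Extract the radiomics feature battery from one masked image
#'
#' The image and mask must already live on a common (typically isotropic)
#' grid. Intensity and texture classes are computed on every derived image the
#' configured filters produce; shape descriptors only on the original image.
#' Values may be `NaN` for degenerate regions (e.g. a single gray level);
#' the cohort layer drops such columns before modeling.
#'
#' @param volume an [mri_volume()].
#' @param mask a [binary_mask()] on the same grid with at least 2 voxels.
#' @param config an [extraction_config()].
#' @return named numeric vector; names are `<image>_<class>_<feature>`.
#'   Exactly 1409 values under the pinned default configuration.
#' @export
extract_features <- function(volume, mask, config = extraction_config()) {
  stopifnot(inherits(volume, "mri_volume"), inherits(mask, "binary_mask"),
            inherits(config, "extraction_config"))
  check_same_grid(volume, mask)
  if (sum(mask$values) < 2) stop("mask has fewer than 2 voxels; texture undefined")
  # crop to the mask bounding box with a 2-voxel pad: filters are local
  cr <- .crop_pair(volume$values, mask$values, pad = 2L)
  inmask <- cr$mask != 0
  images <- derive_images(cr$values, volume$spacing_mm, config$filters,
                          config$log_sigma_mm)
  out <- numeric(0)
  for (img_name in names(images)) {
    img <- images[[img_name]]
    lv <- discretize_gray_levels(img, inmask, config$bin_width)
    x <- img[inmask]
    for (cls in intersect(config$feature_classes, names(.intensity_classes()))) {
      f <- switch(cls,
        firstorder = firstorder_features(x, lv[inmask], prod(volume$spacing_mm)),
        glcm = glcm_features(lv),
        glrlm = glrlm_features(lv),
        glszm = glszm_features(lv),
        gldm = gldm_features(lv),
        ngtdm = ngtdm_features(lv))
      names(f) <- paste(img_name, cls, names(f), sep = "_")
      out <- c(out, f)
    }
  }
  if ("shape" %in% config$feature_classes &&
      (!config$shape_on_original_only || "original" %in% config$filters)) {
    f <- shape_features(cr$mask, mask$spacing_mm)
    names(f) <- paste("original", "shape", names(f), sep = "_")
    out <- c(out, f)
  }
  out
}

.crop_pair <- function(values, maskvals, pad = 2L) {
  idx <- which(maskvals != 0, arr.ind = TRUE)
  dm <- dim(maskvals)
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, dm)
  list(values = values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
       mask = maskvals[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE])
}

#' Build a feature key string
#'
#' Column keys carry provenance as 6 `|`-separated fields:
#' `phase|compartment|resolution_mm|filter|class|name`. The reader dimension
#' is carried by the table itself (one table per reader, identical keys), and
#' as a 7th leading field in the long-format CSV export.
#' @param phase,compartment,resolution_mm,filter,feature_class,feature_name
#'   key fields.
#' @return character key.
#' @export
feature_key <- function(phase, compartment, resolution_mm, filter,
                        feature_class, feature_name) {
  paste(phase, compartment, resolution_mm, filter, feature_class,
        feature_name, sep = "|")
}

#' Parse feature keys into a provenance data frame
#' @param keys character vector of keys as produced by [extract_cohort()].
#' @return data.frame with columns phase, compartment, resolution_mm,
#'   filter, feature_class, feature_name.
#' @export
parse_feature_keys <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  if (any(lengths(parts) != 6L)) stop("malformed feature key(s)")
  m <- do.call(rbind, parts)
  data.frame(phase = m[, 1], compartment = m[, 2],
             resolution_mm = as.numeric(m[, 3]), filter = m[, 4],
             feature_class = m[, 5], feature_name = m[, 6],
             stringsAsFactors = FALSE)
}

#' Extract feature tables for a whole cohort, one per reader
#'
#' For each subject and reader: the tumor mask (T) is the reader's
#' segmentation, the peritumoral ring (TST) is built on the native grid with
#' [build_tst()], and both compartments are paired with both DCE phases and
#' resampled to each configured resolution before extraction.
#'
#' @param cohort list of subjects as produced by [generate_cohort()] (or an
#'   equivalent structure with `id`, `early_volume`, `peak_volume`,
#'   `reader1_mask`, `reader2_mask`).
#' @param config an [extraction_config()].
#' @param dilate_mm,erode_mm ring construction radii passed to [build_tst()].
#' @param verbose print per-subject progress.
#' @return list with elements `reader1` and `reader2`: numeric matrices,
#'   rows = subjects, columns = feature keys (identical between readers).
#' @export
extract_cohort <- function(cohort, config = extraction_config(),
                           dilate_mm = 2, erode_mm = 2, verbose = FALSE) {
  stopifnot(length(cohort) >= 1)
  tables <- list(reader1 = NULL, reader2 = NULL)
  rows <- vapply(cohort, function(s) s$id, "")
  for (si in seq_along(cohort)) {
    s <- cohort[[si]]
    if (verbose) message("extracting subject ", s$id)
    vols <- list(early = s$early_volume, peak = s$peak_volume)
    rvols_by_res <- lapply(config$resolutions_mm, function(res)
      lapply(vols, .resample_volume, target_mm = res))
    names(rvols_by_res) <- as.character(config$resolutions_mm)
    for (reader in 1:2) {
      tmask <- if (reader == 1) s$reader1_mask else s$reader2_mask
      ring <- build_tst(tmask, dilate_mm, erode_mm)
      comps <- list(T = tmask, TST = ring)
      vals <- numeric(0)
      for (res in config$resolutions_mm) {
        rvols <- rvols_by_res[[as.character(res)]]
        for (phase in names(vols)) {
          for (comp in names(comps)) {
            rmask <- .resample_mask(comps[[comp]], res)
            if (sum(rmask$values) == 0)
              stop("subject ", s$id, ": empty mask after resampling (",
                   "reader ", reader, ", ", phase, "/", comp, " @ ", res, " mm)")
            f <- extract_features(rvols[[phase]], rmask, config)
            parts <- strsplit(names(f), "_", fixed = TRUE)
            names(f) <- feature_key(phase, comp, res,
              vapply(parts, `[`, "", 1),
              vapply(parts, `[`, "", 2),
              vapply(parts, function(p) paste(p[-(1:2)], collapse = "_"), ""))
            vals <- c(vals, f)
          }
        }
      }
      key <- paste0("reader", reader)
      if (is.null(tables[[key]])) {
        tables[[key]] <- matrix(NA_real_, nrow = length(cohort), ncol = length(vals),
                                dimnames = list(rows, names(vals)))
      }
      tables[[key]][si, ] <- vals
    }
  }
  tables
}

#' Z-score feature columns, fitting on a subject subset
#'
#' Centering/scaling parameters are learned on `fit_rows` (sample standard
#' deviation, n - 1 denominator) and applied unchanged to all rows. Columns
#' with zero variance over the fit rows are dropped with a warning.
#'
#' @param table numeric matrix, rows = subjects.
#' @param fit_rows row names or indices to fit on; default all rows.
#' @return transformed matrix with attributes `center`, `scale`,
#'   `dropped` (keys of zero-variance columns).
#' @export
zscore_columns <- function(table, fit_rows = rownames(table)) {
  stopifnot(is.matrix(table), length(fit_rows) >= 1)
  fit <- table[fit_rows, , drop = FALSE]
  nf <- nrow(fit)
  ctr <- colMeans(fit)
  scl <- sqrt(pmax(colSums(fit^2) - nf * ctr^2, 0) / (nf - 1))
  keep <- is.finite(scl) & scl > 0
  if (any(!keep))
    warning(sum(!keep), " zero-variance column(s) dropped before z-scoring")
  out <- sweep(sweep(table[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  attr(out, "center") <- ctr[keep]
  attr(out, "scale") <- scl[keep]
  attr(out, "dropped") <- colnames(table)[!keep]
  out
}

#' Drop columns that are not finite for every subject
#'
#' Non-computable features (degenerate regions, log of non-positive values)
#' yield NaN; they are removed cohort-wide and symmetrically across readers.
#'
#' @param tables list of per-reader matrices as from [extract_cohort()].
#' @return same structure with the union of non-finite columns removed.
#' @export
drop_nonfinite_columns <- function(tables) {
  bad <- Reduce(`|`, lapply(tables, function(t) apply(!is.finite(t), 2, any)))
  lapply(tables, function(t) t[, !bad, drop = FALSE])
}

#' Write a per-reader feature table pair as CSV
#' @param tables list with `reader1`, `reader2` matrices.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_tables <- function(tables, path) {
  long <- do.call(rbind, lapply(names(tables), function(r) {
    t <- tables[[r]]
    data.frame(reader = r,
               subject = rep(rownames(t), ncol(t)),
               key = rep(colnames(t), each = nrow(t)),
               value = as.vector(t), stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
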