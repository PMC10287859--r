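# Radiomics feature battery: counts, analytic phantoms, invariances.

test_that("pinned default config yields exactly 1409 features with the documented decomposition", {
  m <- make_sphere_mask(6, n = 17)
  vol <- make_noise_volume(dim(m$values), seed = 3)
  f <- extract_features(vol, m)
  expect_length(f, 1409)
  expect_false(any(duplicated(names(f))))

  parts <- strsplit(names(f), "_", fixed = TRUE)
  img <- vapply(parts, `[`, "", 1)
  cls <- vapply(parts, `[`, "", 2)
  # 15 feature-yielding image types: original + 8 wavelet + 6 other filters
  expect_equal(length(unique(img)), 15L)
  expect_equal(sum(grepl("^wavelet-", unique(img))), 8L)
  # 93 intensity features per image type, 14 shape on original only
  expect_equal(as.vector(table(cls)[c("firstorder", "glcm", "glrlm", "glszm",
                                      "gldm", "ngtdm")]),
               c(18, 24, 16, 16, 14, 5) * 15)
  expect_equal(sum(cls == "shape"), 14L)
  expect_equal(15 * 93 + 14, 1409)
})

test_that("restricted configs count as expected and errors are raised", {
  m <- make_sphere_mask(5, n = 15)
  vol <- make_noise_volume(dim(m$values), seed = 5)
  f <- extract_features(vol, m, extraction_config(filters = "original",
                                                  feature_classes = "shape"))
  expect_length(f, 14)
  f2 <- extract_features(vol, m, extraction_config(filters = "original",
    feature_classes = c("firstorder", "glcm", "glrlm", "glszm", "gldm", "ngtdm")))
  expect_length(f2, 93)

  expect_error(extraction_config(filters = "fourier"), "unknown filter")
  expect_error(extraction_config(feature_classes = "fractal"), "unknown feature class")
  expect_error(extraction_config(bin_width = 0), "bin_width")
  tiny <- binary_mask(array(c(1, rep(0, 26)), c(3, 3, 3)), c(1, 1, 1))
  vol3 <- make_noise_volume(c(3, 3, 3))
  expect_error(extract_features(vol3, tiny), "fewer than 2")
})

test_that("constant-intensity region gives zero spread, entropy and contrast", {
  m <- make_sphere_mask(4, n = 13)
  vol <- mri_volume(array(7, dim(m$values)), c(1, 1, 1))
  f <- extract_features(vol, m, extraction_config(
    filters = "original", feature_classes = c("firstorder", "glcm")))
  expect_equal(unname(f["original_firstorder_Variance"]), 0)
  expect_equal(unname(f["original_firstorder_Entropy"]), 0)
  expect_equal(unname(f["original_firstorder_Uniformity"]), 1)
  expect_equal(unname(f["original_glcm_Contrast"]), 0)
  expect_equal(unname(f["original_glcm_MaximumProbability"]), 1)
})

test_that("GLCM and first-order match a brute-force oracle on a checker pattern", {
  # 4x4x1 in-plane checkerboard of intensities 0 / 30 (bin width 25 -> levels 1, 2)
  dm <- c(6, 6, 3)
  vals <- array(0, dm); msk <- array(0L, dm)
  for (x in 2:5) for (y in 2:5) {
    msk[x, y, 2] <- 1L
    vals[x, y, 2] <- 30 * ((x + y) %% 2)
  }
  vol <- mri_volume(vals, c(1, 1, 1)); m <- binary_mask(msk, c(1, 1, 1))
  f <- extract_features(vol, m, extraction_config(
    filters = "original", feature_classes = c("firstorder", "glcm")))

  # first-order, by hand: 8 voxels at 0, 8 at 30
  expect_equal(unname(f["original_firstorder_Mean"]), 15)
  expect_equal(unname(f["original_firstorder_Variance"]), 225)
  expect_equal(unname(f["original_firstorder_Entropy"]), 1)
  expect_equal(unname(f["original_firstorder_Uniformity"]), 0.5)
  expect_equal(unname(f["original_firstorder_Energy"]), 8 * 900)

  # brute-force co-occurrence enumeration over all voxel pairs per direction
  dirs <- perirad:::.directions13()
  lv <- ifelse(msk == 1L, ifelse(vals >= 25, 2L, 1L), NA_integer_)
  contr <- c(); jent <- c(); maxp <- c(); acorr <- c()
  for (r in seq_len(nrow(dirs))) {
    d <- dirs[r, ]
    cnt <- matrix(0, 2, 2)
    for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
      a <- lv[x, y, z]
      nx <- x + d[1]; ny <- y + d[2]; nz <- z + d[3]
      if (is.na(a) || nx < 1 || ny < 1 || nz < 1 ||
          nx > dm[1] || ny > dm[2] || nz > dm[3]) next
      b <- lv[nx, ny, nz]
      if (is.na(b)) next
      cnt[a, b] <- cnt[a, b] + 1
      cnt[b, a] <- cnt[b, a] + 1           # symmetric
    }
    if (sum(cnt) == 0) next
    p <- cnt / sum(cnt)
    contr <- c(contr, sum(outer(1:2, 1:2, `-`)^2 * p))
    pe <- p[p > 0]
    jent <- c(jent, -sum(pe * log2(pe)))
    maxp <- c(maxp, max(p))
    acorr <- c(acorr, sum(outer(1:2, 1:2) * p))
  }
  expect_equal(unname(f["original_glcm_Contrast"]), mean(contr))
  expect_equal(unname(f["original_glcm_JointEntropy"]), mean(jent))
  expect_equal(unname(f["original_glcm_MaximumProbability"]), mean(maxp))
  expect_equal(unname(f["original_glcm_Autocorrelation"]), mean(acorr))
})

test_that("GLRLM and GLSZM match hand-computed values on a striped strip", {
  # single row of 6 in-mask voxels with levels 1,1,2,2,2,1 along x
  dm <- c(8, 3, 3)
  vals <- array(0, dm); msk <- array(0L, dm)
  lvls <- c(1, 1, 2, 2, 2, 1)
  for (i in seq_along(lvls)) { msk[i + 1, 2, 2] <- 1L; vals[i + 1, 2, 2] <- 25 * (lvls[i] - 1) }
  vol <- mri_volume(vals, c(1, 1, 1)); m <- binary_mask(msk, c(1, 1, 1))
  f <- extract_features(vol, m, extraction_config(
    filters = "original", feature_classes = c("glrlm", "glszm")))
  # along x: runs 2,3,1 -> Nz = 3, run% = 0.5; other 12 directions: six
  # length-1 runs -> run% = 1; features average over directions
  expect_equal(unname(f["original_glrlm_RunPercentage"]), (0.5 + 12) / 13)
  # zones (26-connectivity): {1,1}, {2,2,2}, {1} -> sizes 2,3,1
  expect_equal(unname(f["original_glszm_ZonePercentage"]), 3 / 6)
  expect_equal(unname(f["original_glszm_SmallAreaEmphasis"]),
               (1 / 4 + 1 / 9 + 1) / 3)
  expect_equal(unname(f["original_glszm_GrayLevelNonUniformity"]),
               (2^2 + 1^2) / 3)
})

test_that("GLDM matches the analytic dependence profile of a solid block", {
  # full 3x3x3 block, constant intensity: dependence sizes are known exactly
  dm <- c(5, 5, 5)
  msk <- array(0L, dm); msk[2:4, 2:4, 2:4] <- 1L
  vol <- mri_volume(array(5, dm), c(1, 1, 1))
  f <- extract_features(vol, binary_mask(msk, c(1, 1, 1)),
                        extraction_config(filters = "original",
                                          feature_classes = "gldm"))
  # 8 corners: 7+1, 12 edges: 11+1, 6 faces: 17+1, 1 centre: 26+1
  sizes <- c(rep(8, 8), rep(12, 12), rep(18, 6), 27)
  expect_equal(unname(f["original_gldm_LargeDependenceEmphasis"]),
               mean(sizes^2))
  expect_equal(unname(f["original_gldm_SmallDependenceEmphasis"]),
               mean(1 / sizes^2))
})

test_that("z-scoring pins the n-1 convention and handles degenerate columns", {
  t <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), d = c(0, 10, 20))
  rownames(t) <- c("s1", "s2", "s3")
  expect_warning(z <- zscore_columns(t), "zero-variance")
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))        # sample sd = 1
  expect_false("b" %in% colnames(z))
  expect_equal(attr(z, "dropped"), "b")
  # idempotence up to floating error
  z2 <- suppressWarnings(zscore_columns(z))
  expect_equal(unname(z2[, "a"]), unname(z[, "a"]), tolerance = 1e-12)
  # fit on a subset, apply to all rows
  z3 <- suppressWarnings(zscore_columns(t, fit_rows = c("s1", "s2")))
  expect_equal(unname(z3[, "a"]), (c(1, 2, 3) - 1.5) / stats::sd(c(1, 2)))
})

test_that("texture features are intensity-shift invariant; first-order survive rotation", {
  m <- make_sphere_mask(5, n = 15)
  vol <- make_noise_volume(dim(m$values), seed = 8)
  cfg <- extraction_config(filters = "original",
    feature_classes = c("glcm", "glrlm", "glszm", "gldm", "ngtdm"))
  f1 <- extract_features(vol, m, cfg)
  shifted <- mri_volume(vol$values + 137, vol$spacing_mm)
  expect_equal(extract_features(shifted, m, cfg), f1)

  cfg_fo <- extraction_config(filters = "original", feature_classes = "firstorder")
  f_fo <- extract_features(vol, m, cfg_fo)
  rot <- function(a) aperm(a[, dim(a)[2]:1, , drop = FALSE], c(2, 1, 3))
  vol_r <- mri_volume(rot(vol$values), vol$spacing_mm)
  m_r <- binary_mask(rot(m$values), m$spacing_mm)
  expect_equal(extract_features(vol_r, m_r, cfg_fo), f_fo)
})

test_that("identical reader masks give identical cohort tables; keys parse", {
  co <- generate_cohort(tiny_cohort_config(seed = 6, n_subjects = 4))
  for (i in seq_along(co)) co[[i]]$reader2_mask <- co[[i]]$reader1_mask
  tb <- extract_cohort(co, reduced_extraction_config())
  expect_identical(tb$reader1, tb$reader2)
  expect_equal(nrow(tb$reader1), 4)
  info <- parse_feature_keys(colnames(tb$reader1))
  expect_setequal(unique(info$phase), c("early", "peak"))
  expect_setequal(unique(info$compartment), c("T", "TST"))
  expect_true(all(info$resolution_mm == 2))
  # 2 phases x 2 compartments x 1 resolution x 18 first-order features
  expect_equal(ncol(tb$reader1), 2 * 2 * 18)
})
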