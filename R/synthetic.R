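# Synthetic 3D phantom cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: a
# ~62-subject cohort with ~24% high-risk prevalence, ellipsoidal enhancing
# lesions on two DCE phases ("early", "peak"), class-linked intratumoral
# texture and peritumoral rim enhancement, and two readers whose segmentations
# differ by small boundary perturbations. It is a stated world, not a model of
# MR physics: no coil/bias fields, no pharmacokinetics, single lesion per
# subject.
#
# Class effects (defaults document the stated world; see the methods vignette):
#   - texture: correlated noise inside the lesion; amplitude and correlation
#     length are both scaled by (1 + 0.25 * texture_effect) for positives.
#   - rim: voxel values in a 4-mm shell outside the true boundary are
#     multiplied by (1 + 0.08 * rim_effect) for positives, on both phases.
# With both effects at 0 the image distribution is identical across classes.

#' Cohort generator configuration
#'
#' @param n_subjects number of subjects (>= 4).
#' @param prevalence fraction of high-risk subjects in (0, 1); the positive
#'   count is `round(n_subjects * prevalence)`.
#' @param grid_shape integer length-3 voxel grid.
#' @param spacing_mm per-axis voxel size in mm (default anisotropic 1x1x2).
#' @param lesion_radius_mm length-2 min/max of the ellipsoid semi-axes (mm).
#' @param texture_effect nonnegative scalar scaling the class contrast of
#'   intratumoral texture (0 = no class signal in texture).
#' @param rim_effect nonnegative scalar scaling the class contrast of
#'   peritumoral rim enhancement (0 = none).
#' @param enhancement_ratio peak-to-early lesion enhancement ratio (> 1).
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param reader_perturb_mm boundary perturbation magnitude between readers.
#' @param seed integer RNG seed.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 62, prevalence = 15 / 62,
                          grid_shape = c(64, 64, 64),
                          spacing_mm = c(1, 1, 2),
                          lesion_radius_mm = c(6, 10),
                          texture_effect = 1, rim_effect = 1,
                          enhancement_ratio = 1.6, noise_sd = 10,
                          reader_perturb_mm = 1, seed = 1) {
  chk <- function(ok, field, msg) if (!ok) stop("invalid `", field, "`: ", msg)
  chk(is.numeric(n_subjects) && n_subjects >= 4, "n_subjects", "must be >= 4")
  chk(is.numeric(prevalence) && prevalence > 0 && prevalence < 1,
      "prevalence", "must be in (0, 1)")
  chk(length(grid_shape) == 3 && all(grid_shape >= 8), "grid_shape",
      "must be 3 values >= 8")
  chk(length(spacing_mm) == 3 && all(spacing_mm > 0), "spacing_mm",
      "must be 3 positive values")
  chk(length(lesion_radius_mm) == 2 && all(lesion_radius_mm > 0) &&
        lesion_radius_mm[1] <= lesion_radius_mm[2], "lesion_radius_mm",
      "must be increasing positive min/max")
  chk(texture_effect >= 0, "texture_effect", "must be >= 0")
  chk(rim_effect >= 0, "rim_effect", "must be >= 0")
  chk(enhancement_ratio > 1, "enhancement_ratio", "must be > 1")
  chk(noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(reader_perturb_mm >= 0, "reader_perturb_mm", "must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects), prevalence = prevalence,
                 grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
                 lesion_radius_mm = lesion_radius_mm,
                 texture_effect = texture_effect, rim_effect = rim_effect,
                 enhancement_ratio = enhancement_ratio, noise_sd = noise_sd,
                 reader_perturb_mm = reader_perturb_mm, seed = as.integer(seed)),
            class = "cohort_config")
}

# smoothed, unit-variance correlated noise field
.correlated_field <- function(dm, spacing, sigma_mm) {
  f <- array(stats::rnorm(prod(dm)), dim = dm)
  for (a in 1:3) {
    sv <- sigma_mm / spacing[a]
    if (dm[a] >= 3 && sv > 0.3) f <- .smooth_axis(f, a, .gauss_kernel(sv))
  }
  s <- stats::sd(as.vector(f))
  if (s > 0) f <- f / s
  f
}

#' Perturb a segmentation the way a second reader would
#'
#' Applies random local dilations/erosions (spherical patches of radius
#' `perturb_mm` centred on boundary voxels), emulating small inter-reader
#' boundary disagreements. `perturb_mm = 0` returns the input unchanged.
#'
#' @param true_mask a nonempty [binary_mask()].
#' @param perturb_mm patch radius in mm (>= 0).
#' @param seed integer seed (local RNG, does not disturb the global stream).
#' @param n_patches number of boundary patches (default 8).
#' @return perturbed `binary_mask` (never empty).
#' @export
simulate_reader_mask <- function(true_mask, perturb_mm, seed, n_patches = 8) {
  stopifnot(inherits(true_mask, "binary_mask"))
  if (sum(true_mask$values) == 0) stop("cannot perturb an empty mask")
  if (perturb_mm <= 0) return(true_mask)
  rs <- .with_local_seed(seed)
  on.exit(rs())
  m <- true_mask$values != 0
  dm <- dim(m)
  interior <- m
  for (a in 1:3) interior <- interior & .shift_mask_zero(m, a, 1L) & .shift_mask_zero(m, a, -1L)
  bnd <- which(m & !interior, arr.ind = TRUE)
  if (nrow(bnd) == 0) bnd <- which(m, arr.ind = TRUE)
  el <- ball_element(perturb_mm, true_mask$spacing_mm)
  out <- m
  for (k in seq_len(n_patches)) {
    seed_vox <- bnd[sample.int(nrow(bnd), 1), ]
    grow <- stats::runif(1) < 0.5
    tgt <- sweep(el, 2, as.integer(seed_vox), `+`)
    keep <- tgt[, 1] >= 1 & tgt[, 1] <= dm[1] & tgt[, 2] >= 1 &
      tgt[, 2] <= dm[2] & tgt[, 3] >= 1 & tgt[, 3] <= dm[3]
    tgt <- tgt[keep, , drop = FALSE]
    lin <- tgt[, 1] + (tgt[, 2] - 1L) * dm[1] + (tgt[, 3] - 1L) * dm[1] * dm[2]
    if (grow) out[lin] <- TRUE else out[lin] <- FALSE
  }
  if (!any(out)) out <- m  # never return an empty segmentation
  binary_mask(out, true_mask$spacing_mm, true_mask$origin_mm)
}

.with_local_seed <- function(seed) {
  force(seed)  # must evaluate before saving state: callers pass runif() draws
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Draw recurrence scores consistent with binary risk labels
#'
#' Positives receive integer scores in 26..100, negatives in 0..25, so
#' binarising at the >25 cutoff reproduces the labels exactly.
#'
#' @param labels binary (0/1) vector.
#' @param seed integer seed (local RNG).
#' @return integer vector of recurrence scores.
#' @export
assign_scores <- function(labels, seed) {
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  rs <- .with_local_seed(seed)
  on.exit(rs())
  ifelse(labels == 1,
         sample(26:100, length(labels), replace = TRUE),
         sample(0:25, length(labels), replace = TRUE))
}

#' Generate a synthetic phantom cohort
#'
#' @param config a [cohort_config()].
#' @return list of subjects; each has `id`, `early_volume`, `peak_volume`,
#'   `true_mask`, `reader1_mask`, `reader2_mask`, `recurrence_score`, `label`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  rs <- .with_local_seed(config$seed)
  on.exit(rs())
  n <- config$n_subjects
  npos <- round(n * config$prevalence)
  if (npos < 1 || npos > n - 1)
    stop("invalid `prevalence`: yields ", npos, " positives out of ", n)
  labels <- integer(n)
  labels[sample.int(n, npos)] <- 1L
  scores <- assign_scores(labels, seed = stats::runif(1, 1, 2^30))
  dm <- config$grid_shape
  sp <- config$spacing_mm
  extent <- dm * sp
  background <- 100
  lesion_signal <- 150
  cohort <- vector("list", n)
  # physical voxel-centre coordinates, reused across subjects
  ax <- lapply(1:3, function(a) (seq_len(dm[a]) - 1) * sp[a])
  for (i in seq_len(n)) {
    lab <- labels[i]
    centre <- extent / 2 + stats::runif(3, -0.05, 0.05) * extent
    semi <- stats::runif(3, config$lesion_radius_mm[1], config$lesion_radius_mm[2])
    dx2 <- outer(outer((ax[[1]] - centre[1])^2 / semi[1]^2,
                       (ax[[2]] - centre[2])^2 / semi[2]^2, `+`),
                 (ax[[3]] - centre[3])^2 / semi[3]^2, `+`)
    lesion <- dx2 <= 1
    if (!any(lesion)) stop("degenerate lesion (empty); enlarge grid or radii")
    tmask <- binary_mask(lesion, sp)
    # class-dependent texture: same random field, label-scaled amplitude/length
    tex_scale <- 1 + 0.25 * config$texture_effect * lab
    field <- .correlated_field(dm, sp, sigma_mm = 1.5 * tex_scale)
    texture_amp <- 40 * tex_scale
    # analytic 4-mm outer shell (ellipsoid semi-axes grown by 4 mm); cheaper
    # than voxel dilation and adequate for a generator
    dx2_out <- outer(outer((ax[[1]] - centre[1])^2 / (semi[1] + 4)^2,
                           (ax[[2]] - centre[2])^2 / (semi[2] + 4)^2, `+`),
                     (ax[[3]] - centre[3])^2 / (semi[3] + 4)^2, `+`)
    rim <- dx2_out <= 1 & !lesion
    rim_gain <- 1 + 0.08 * config$rim_effect * lab
    noise_e <- array(stats::rnorm(prod(dm), 0, config$noise_sd), dim = dm)
    noise_p <- array(stats::rnorm(prod(dm), 0, config$noise_sd), dim = dm)
    base_e <- background + lesion * lesion_signal + lesion * texture_amp * field
    base_p <- background + lesion * lesion_signal * config$enhancement_ratio +
      lesion * texture_amp * field
    base_e[rim] <- base_e[rim] * rim_gain
    base_p[rim] <- base_p[rim] * rim_gain
    early <- mri_volume(base_e + noise_e, sp)
    peak <- mri_volume(base_p + noise_p, sp)
    r1 <- simulate_reader_mask(tmask, config$reader_perturb_mm,
                               seed = stats::runif(1, 1, 2^30))
    r2 <- simulate_reader_mask(tmask, config$reader_perturb_mm,
                               seed = stats::runif(1, 1, 2^30))
    cohort[[i]] <- list(id = sprintf("S%03d", i), early_volume = early,
                        peak_volume = peak, true_mask = tmask,
                        reader1_mask = r1, reader2_mask = r2,
                        recurrence_score = scores[i], label = lab)
  }
  cohort
}

#' Write a cohort to disk (NIfTI volumes/masks + labels CSV)
#'
#' @param cohort list from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly. Files per subject:
#'   `<id>_early.nii.gz`, `<id>_peak.nii.gz`, `<id>_reader1.nii.gz`,
#'   `<id>_reader2.nii.gz`; plus `cohort.csv` (id, recurrence_score, label).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort) {
    write_nifti(s$early_volume, file.path(dir, paste0(s$id, "_early.nii.gz")))
    write_nifti(s$peak_volume, file.path(dir, paste0(s$id, "_peak.nii.gz")))
    write_nifti(s$reader1_mask, file.path(dir, paste0(s$id, "_reader1.nii.gz")))
    write_nifti(s$reader2_mask, file.path(dir, paste0(s$id, "_reader2.nii.gz")))
  }
  df <- data.frame(id = vapply(cohort, `[[`, "", "id"),
                   recurrence_score = vapply(cohort, `[[`, 0L, "recurrence_score"),
                   label = vapply(cohort, `[[`, 0L, "label"))
  utils::write.csv(df, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing per-subject NIfTI files and `cohort.csv`
#'   (or a labels CSV passed via `labels_csv`). A `recurrence_score` column is
#'   binarised at the cutoff; otherwise a `label` column is used as-is.
#' @param labels_csv path to the labels CSV (default `dir/cohort.csv`).
#' @param score_cutoff recurrence-score cutoff for the high-risk class.
#' @return cohort list in the [generate_cohort()] format (`true_mask` is set
#'   to the reader-1 mask, which is unused downstream).
#' @export
read_cohort <- function(dir, labels_csv = file.path(dir, "cohort.csv"),
                        score_cutoff = 25) {
  if (!file.exists(labels_csv)) stop("labels CSV not found: ", labels_csv)
  df <- utils::read.csv(labels_csv, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("labels CSV must have an `id` column")
  if ("recurrence_score" %in% names(df)) {
    labels <- as.integer(df$recurrence_score > score_cutoff)
    scores <- as.integer(df$recurrence_score)
  } else if ("label" %in% names(df)) {
    labels <- as.integer(df$label)
    scores <- ifelse(labels == 1L, score_cutoff + 1L, score_cutoff)
  } else stop("labels CSV needs a `recurrence_score` or `label` column")
  lapply(seq_len(nrow(df)), function(i) {
    id <- df$id[i]
    pth <- function(sfx) {
      for (ext in c(".nii.gz", ".nii")) {
        p <- file.path(dir, paste0(id, "_", sfx, ext))
        if (file.exists(p)) return(p)
      }
      stop("missing ", sfx, " image for subject ", id)
    }
    list(id = id,
         early_volume = read_nifti(pth("early")),
         peak_volume = read_nifti(pth("peak")),
         true_mask = read_nifti(pth("reader1"), as_mask = TRUE),
         reader1_mask = read_nifti(pth("reader1"), as_mask = TRUE),
         reader2_mask = read_nifti(pth("reader2"), as_mask = TRUE),
         recurrence_score = scores[i], label = labels[i])
  })
}
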