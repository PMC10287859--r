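# Shared fixtures and independent brute-force oracles.

# binary sphere on a cubic grid (radius in voxels == mm when spacing is 1 mm)
make_sphere_mask <- function(radius_vox, n = 2L * radius_vox + 11L,
                             spacing = c(1, 1, 1)) {
  cc <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  v <- array((g$x - cc)^2 + (g$y - cc)^2 + (g$z - cc)^2 <= radius_vox^2,
             dim = c(n, n, n))
  binary_mask(v, spacing)
}

make_noise_volume <- function(dm, spacing = c(1, 1, 1), mean = 100, sd = 50,
                              seed = 1) {
  set.seed(seed)
  mri_volume(array(stats::rnorm(prod(dm), mean, sd), dim = dm), spacing)
}

# direct per-voxel neighbourhood evaluation of dilation/erosion (oracle)
brute_morph <- function(mask, radius_mm, op = c("dilate", "erode")) {
  op <- match.arg(op)
  v <- mask$values != 0
  dm <- dim(v)
  el <- ball_element(radius_mm, mask$spacing_mm)
  out <- array(FALSE, dim = dm)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    nb <- cbind(x + el[, 1], y + el[, 2], z + el[, 3])
    inside <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 &
      nb[, 2] <= dm[2] & nb[, 3] >= 1 & nb[, 3] <= dm[3]
    vals <- rep(FALSE, nrow(nb))
    vals[inside] <- v[nb[inside, , drop = FALSE]]
    out[x, y, z] <- if (op == "dilate") any(vals) else all(vals)
  }
  out
}

# small fast synthetic cohort for pipeline-level tests
tiny_cohort_config <- function(seed, n_subjects = 16, texture_effect = 1,
                               rim_effect = 1, ...) {
  cohort_config(n_subjects = n_subjects,
                prevalence = 0.25,
                grid_shape = c(16, 16, 16), spacing_mm = c(2, 2, 2),
                lesion_radius_mm = c(5, 8),
                texture_effect = texture_effect, rim_effect = rim_effect,
                seed = seed, ...)
}

reduced_extraction_config <- function() {
  extraction_config(filters = "original", feature_classes = "firstorder",
                    resolutions_mm = 2)
}

# full pipeline at desk scale: n = 62, prevalence 15/62, reduced feature
# config (original filter, first-order, native 2-mm resolution), combination
# (a), k_grid 1:3, 1e4 permutations. Used by the type-I and signal-recovery
# acceptance criteria.
run_reduced_pipeline <- function(seed, texture_effect, rim_effect,
                                 n_perm = 1e4) {
  cfg <- run_config(
    cohort = cohort_config(n_subjects = 62, prevalence = 15 / 62,
                           grid_shape = c(16, 16, 16), spacing_mm = c(2, 2, 2),
                           lesion_radius_mm = c(5, 8),
                           texture_effect = texture_effect,
                           rim_effect = rim_effect, seed = seed),
    extraction = reduced_extraction_config(),
    combination = "a", n_perm = n_perm, perm_seed = seed, k_grid = 1:3)
  r <- suppressWarnings(run_pipeline(cfg))$combinations$a
  c(auc = r$auc, p = r$p_empirical)
}
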