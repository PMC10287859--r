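# Synthetic phantom cohort generator.

test_that("cohort has the requested size, prevalence and determinism", {
  cfg <- cohort_config(n_subjects = 62, prevalence = 15 / 62,
                       grid_shape = c(12, 12, 12), spacing_mm = c(2, 2, 2),
                       lesion_radius_mm = c(4, 6), seed = 5)
  co <- generate_cohort(cfg)
  labs <- vapply(co, `[[`, 0L, "label")
  expect_length(co, 62)
  expect_equal(sum(labs), 15)
  expect_equal(sum(labs == 0), 47)
  expect_identical(co, generate_cohort(cfg))   # same seed, same world
  # different seed, different world
  co2 <- generate_cohort(cohort_config(n_subjects = 62, prevalence = 15 / 62,
                                       grid_shape = c(12, 12, 12),
                                       spacing_mm = c(2, 2, 2),
                                       lesion_radius_mm = c(4, 6), seed = 6))
  expect_false(identical(co, co2))
})

test_that("subject invariants hold: masks, enhancement, label consistency", {
  co <- generate_cohort(tiny_cohort_config(seed = 2, n_subjects = 8))
  for (s in co) {
    expect_gt(mask_voxel_count(s$true_mask), 0)
    expect_gt(dice_coefficient(s$true_mask, s$reader1_mask), 0)
    expect_gt(dice_coefficient(s$true_mask, s$reader2_mask), 0)
    inles <- s$true_mask$values == 1
    expect_gt(mean(s$peak_volume$values[inles]),
              mean(s$early_volume$values[inles]))
    expect_identical(s$label, as.integer(s$recurrence_score > 25))
  }
  # the two readers differ from each other (perturbation is applied)
  d <- vapply(co, function(s)
    dice_coefficient(s$reader1_mask, s$reader2_mask), 0)
  expect_true(any(d < 1))
})

test_that("invalid configurations name the offending field", {
  expect_error(cohort_config(n_subjects = 2), "n_subjects")
  expect_error(cohort_config(prevalence = 0), "prevalence")
  expect_error(cohort_config(spacing_mm = c(1, 0, 1)), "spacing_mm")
  expect_error(cohort_config(enhancement_ratio = 1), "enhancement_ratio")
  expect_error(cohort_config(reader_perturb_mm = -1), "reader_perturb_mm")
})

test_that("reader-mask perturbation behaves as specified", {
  m <- make_sphere_mask(10)    # 10-mm sphere on a 1-mm grid
  expect_identical(simulate_reader_mask(m, 0, seed = 1), m)
  r <- simulate_reader_mask(m, 1, seed = 1)
  expect_gt(mask_voxel_count(r), 0)
  expect_gt(dice_coefficient(m, r), 0.8)
  # displacement grows with the perturbation radius
  r3 <- simulate_reader_mask(m, 3, seed = 1)
  expect_gt(sum(m$values != r3$values), sum(m$values != r$values))
  empty <- binary_mask(array(0L, dim = c(5, 5, 5)), c(1, 1, 1))
  expect_error(simulate_reader_mask(empty, 1, seed = 1), "empty")
})

test_that("recurrence scores honour the >25 cutoff", {
  expect_error(assign_scores(c(0, 2), seed = 1), "binary")
  s <- assign_scores(c(0, 1), seed = 1)
  expect_lte(s[1], 25); expect_gt(s[2], 25)
  expect_true(all(assign_scores(rep(0, 30), seed = 2) <= 25))
  labs <- c(rep(1, 15), rep(0, 47))
  sc <- assign_scores(labs, seed = 3)
  expect_equal(sum(sc > 25), 15)
  expect_identical(as.integer(sc > 25), as.integer(labs))
})

test_that("zero effect sizes leave image statistics independent of label", {
  # replicate cohorts; lesion-mean difference between classes centres at 0
  diffs <- vapply(1:10, function(seed) {
    co <- generate_cohort(tiny_cohort_config(seed = seed, n_subjects = 12,
                                             texture_effect = 0, rim_effect = 0))
    labs <- vapply(co, `[[`, 0L, "label")
    stat <- vapply(co, function(s) stats::sd(s$peak_volume$values[s$true_mask$values == 1]), 0)
    mean(stat[labs == 1]) - mean(stat[labs == 0])
  }, 0)
  expect_lt(abs(mean(diffs)), 2 * stats::sd(diffs) / sqrt(length(diffs)) + 1)
  # and a nonzero texture effect shifts within-lesion variability upward
  diffs1 <- vapply(1:10, function(seed) {
    co <- generate_cohort(tiny_cohort_config(seed = seed, n_subjects = 12,
                                             texture_effect = 3, rim_effect = 0))
    labs <- vapply(co, `[[`, 0L, "label")
    stat <- vapply(co, function(s) stats::sd(s$peak_volume$values[s$true_mask$values == 1]), 0)
    mean(stat[labs == 1]) - mean(stat[labs == 0])
  }, 0)
  expect_gt(mean(diffs1), mean(diffs))
})

test_that("out-of-sample AUC is non-decreasing in the texture effect", {
  # 3 effect levels x 20 seeds; compare mean AUC across levels on small,
  # fast cohorts (the property is about ordering, not absolute performance)
  mean_auc <- vapply(c(0, 1.5, 3), function(eff) {
    aucs <- vapply(1:20, function(seed) {
      cfg <- run_config(
        cohort = cohort_config(n_subjects = 20, prevalence = 0.25,
                               grid_shape = c(16, 16, 16),
                               spacing_mm = c(2, 2, 2),
                               lesion_radius_mm = c(5, 8),
                               texture_effect = eff, rim_effect = 0,
                               seed = seed + 700),
        extraction = reduced_extraction_config(),
        combination = "a", n_perm = 50, perm_seed = 1, k_grid = 1:2)
      suppressWarnings(run_pipeline(cfg))$combinations$a$auc
    }, 0)
    mean(aucs)
  }, 0)
  expect_true(all(diff(mean_auc) >= 0))
})

test_that("cohorts round-trip through NIfTI + CSV on disk", {
  co <- generate_cohort(tiny_cohort_config(seed = 4, n_subjects = 4))
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(co, dir)
  co2 <- read_cohort(dir)
  expect_length(co2, 4)
  for (i in seq_along(co)) {
    expect_equal(co2[[i]]$id, co[[i]]$id)
    expect_identical(co2[[i]]$reader2_mask$values, co[[i]]$reader2_mask$values)
    expect_lt(max(abs(co2[[i]]$peak_volume$values - co[[i]]$peak_volume$values)),
              1e-3)                       # float32 round-trip
    expect_equal(co2[[i]]$label, co[[i]]$label)
  }
})
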