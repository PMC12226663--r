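test_that("straight-tube phantom recovers the analytic annular-cylinder volume", {
  ph <- make_phantom(straight_tube_spec(wall = 3, lumen = 5, noise = 0))
  analytic <- pi * (8^2 - 5^2) * 100 / 1000
  expect_equal(ph$truth$true_length_cm, 10)
  expect_equal(ph$truth$true_volume_mL, analytic, tolerance = 1e-6)
  # voxelized mask volume within 5% of the analytic tube volume
  expect_lt(abs(mask_volume_mL(ph$truth$wall_mask) / analytic - 1), 0.05)
})

test_that("phantom generation is deterministic for a fixed seed", {
  sp <- phantom_spec(noise_sigma = 10, rng_seed = 77)
  a <- make_phantom(sp)
  b <- make_phantom(sp)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$truth$wall_mask$voxels, b$truth$wall_mask$voxels)
  # different seed, different noise
  d <- make_phantom(phantom_spec(noise_sigma = 10, rng_seed = 78))
  expect_false(identical(a$volume$voxels, d$volume$voxels))
})

test_that("constructed wall thickness is recovered by morphometry", {
  ph <- make_phantom(straight_tube_spec(wall = 6, noise = 0))
  expect_equal(ph$truth$true_mean_thickness_mm, 6)
  measured <- mean_wall_thickness(ph$truth$wall_mask)
  expect_lt(abs(measured - 6), 0.5 * 5.0)   # half the largest spacing
})

test_that("wall and lumen are disjoint and mask volume grows with wall thickness", {
  vols <- vapply(c(2, 3.5, 5, 6.5), function(w) {
    ph <- make_phantom(straight_tube_spec(wall = w, noise = 0))
    expect_false(any(ph$truth$wall_mask$voxels & ph$truth$lumen_mask$voxels))
    mask_volume_mL(ph$truth$wall_mask)
  }, numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("invalid phantom specs are rejected with diagnostics", {
  expect_error(phantom_spec(lumen_radius_mm = 0), "positive")
  expect_error(phantom_spec(wall_thickness_mm = -1), "positive")
  # curve running outside the grid
  bad <- phantom_spec(curve_control_points = cbind(c(2, 90), 40, c(20, 120)))
  expect_error(make_phantom(bad), "exits the grid")
})

test_that("rician noise option produces nonnegative magnitude-like intensities", {
  sp <- phantom_spec(noise_sigma = 15, noise_model = "rician", rng_seed = 5)
  ph <- make_phantom(sp)
  expect_true(all(ph$volume$voxels >= 0))
})

test_that("variable-thickness phantoms carry the analytic profile truth", {
  L <- 100
  sp <- straight_tube_spec(noise = 0, grid = c(72L, 72L, 28L))
  sp$wall_fun <- cosine_ramp_thickness(3, 8, L)
  sp$wall_constant <- NA_real_
  ph <- make_phantom(sp)
  expect_equal(ph$truth$true_max_thickness_mm, 8, tolerance = 1e-3)
  # analytic arc-length mean of the cosine ramp is (w0 + w1) / 2
  expect_equal(ph$truth$true_mean_thickness_mm, 5.5, tolerance = 0.2)
})

test_that("null cohort with zero within-subject noise has equal timepoint means", {
  tab <- make_longitudinal_cohort(n_subjects = 8,
                                  timepoint_effects = c(1, 1, 1),
                                  within_subject_sd = 0, agreement_sd = 0,
                                  rng_seed = 11)
  for (m in c("manual_volume_mL", "length_cm")) {
    means <- tapply(tab[[m]], tab$timepoint, mean)
    expect_equal(unname(diff(range(means))), 0, tolerance = 1e-9)
  }
})

test_that("degenerate cohort designs are rejected", {
  expect_error(make_longitudinal_cohort(n_subjects = 1), "at least 2")
  expect_error(make_longitudinal_cohort(between_subject_sd = -1),
               "nonnegative")
  expect_error(make_longitudinal_cohort(timepoint_effects = c(1, 0, 0.5)),
               "\\(0, 1\\]")
})

test_that("empirical timepoint means converge to the specified means", {
  eff <- c(1, 0.59, 0.26)
  n <- 200
  tab <- make_longitudinal_cohort(n_subjects = n, timepoint_effects = eff,
                                  rng_seed = 21)
  # E[y] on the raw scale carries the lognormal factor, equal across
  # timepoints, so mean ratios estimate the shrink factors directly.
  for (m in c("manual_volume_mL", "max_thickness_mm")) {
    means <- tapply(tab[[m]], tab$timepoint, mean)
    sds <- tapply(tab[[m]], tab$timepoint, sd)
    for (j in 2:3) {
      expect_lt(abs(means[j] / means[1] - eff[j]),
                3 * sds[j] / sqrt(n) / means[1] +
                  3 * eff[j] * sds[1] / sqrt(n) / means[1])
    }
  }
})

test_that("mixed-effects fit recovers the simulated declines", {
  set.seed(31)
  seeds <- sample.int(2^31 - 2, 12)
  declines <- sapply(seeds, function(s) {
    tab <- make_longitudinal_cohort(n_subjects = 20,
                                    timepoint_effects = c(1, 0.59, 0.26),
                                    rng_seed = s)
    ct <- fit_change_over_time(tab, "manual_volume_mL")
    100 * (1 - ct$means[c("week6", "month6")] / ct$means[["baseline"]])
  })
  m <- rowMeans(declines)
  se <- apply(declines, 1, sd) / sqrt(ncol(declines))
  expect_lt(abs(m[1] - 41), 3 * se[1] + 2)
  expect_lt(abs(m[2] - 74), 3 * se[2] + 2)
})

test_that("study-style missingness drops the expected visits", {
  tab <- make_longitudinal_cohort(n_subjects = 20, missingness = "study",
                                  rng_seed = 3)
  expect_equal(nrow(tab), 60 - 4)
  expect_equal(sum(tab$subject_id == "S01"), 1)   # baseline only
  expect_false(any(tab$subject_id %in% c("S02", "S03") &
                     tab$timepoint == "month6"))
})

test_that("operator-like mask perturbation changes volume modestly and reproducibly", {
  ph <- make_phantom(straight_tube_spec(noise = 0))
  truth <- ph$truth$wall_mask
  p1 <- perturb_mask(truth, seed = 4)
  p2 <- perturb_mask(truth, seed = 4)
  expect_identical(p1$voxels, p2$voxels)
  rel <- mask_volume_mL(p1) / mask_volume_mL(truth)
  expect_gt(rel, 0.6)
  expect_lt(rel, 1.4)
})
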