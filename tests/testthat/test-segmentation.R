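test_that("uniform ROI with k = 1 yields a single partition spanning the ROI", {
  vol <- image_volume(array(5, c(20, 20, 6)), spacing = c(1, 1, 1))
  cl <- interpolate_centerline(rbind(c(10, 10, 1), c(10, 10, 5)))
  pm <- partition_image(vol, cl, k = 1, roi_radius_mm = 100)
  expect_equal(pm$n_partitions, 1L)
  expect_equal(length(pm$roi_idx), length(vol$voxels))
})

test_that("two homogeneous half-spaces match the intensity-threshold oracle", {
  v <- array(0, c(30, 30, 8)); v[16:30, , ] <- 100
  vol <- image_volume(v, spacing = c(1, 1, 1))
  cl <- interpolate_centerline(rbind(c(15, 15, 1), c(15, 15, 7)))
  pm <- partition_image(vol, cl, k = 2, roi_radius_mm = 60,
                        spatial_weight = 0, seed = 3)
  lab <- pm$labels[pm$roi_idx]
  oracle <- vol$voxels[pm$roi_idx] > 50    # brute-force threshold labels
  agree <- sum(apply(table(lab, oracle), 1, max)) / length(lab)
  expect_gte(agree, 0.99)
})

test_that("partitions are face-connected and deterministic under a fixed seed", {
  ph <- default_phantom()
  cl <- interpolate_centerline(centerline_from_truth(ph$truth, 10))
  pm <- partition_image(ph$volume, cl, k = 30, seed = 6)
  relab <- enterovol:::split_connected(pm$labels, dim(pm$labels))
  expect_equal(max(relab), pm$n_partitions)   # already fully connected

  pm2 <- partition_image(ph$volume, cl, k = 30, seed = 6)
  expect_identical(pm$labels, pm2$labels)

  expect_error(partition_image(ph$volume, cl, k = 1e7), "exceeds the ROI")
  far <- interpolate_centerline(rbind(c(-500, -500, -500), c(-480, -500, -500)))
  expect_error(partition_image(ph$volume, far, roi_radius_mm = 5), "ROI is empty")
})

test_that("no partition of a noise-free phantom badly mixes wall and background", {
  ph <- make_phantom(phantom_spec(noise_sigma = 0))
  cl <- interpolate_centerline(centerline_from_truth(ph$truth, 12))
  pm <- partition_image(ph$volume, cl, k = 40, seed = 2)
  frac <- wall_fraction_targets(pm, ph$truth$wall_mask)
  expect_false(any(frac > 0.2 & frac < 0.8))
})

test_that("feature extraction honours the geometric constructions", {
  ph <- default_phantom()
  cl <- interpolate_centerline(centerline_from_truth(ph$truth, 10))
  pm <- partition_image(ph$volume, cl, k = 25, seed = 4)
  lum <- estimate_lumen_radius(ph$volume, cl)
  ft <- extract_features(pm, ph$volume, lumen_radius_mm = lum)
  expect_equal(nrow(ft), pm$n_partitions)
  expect_true(all(is.finite(as.matrix(ft))))
  expect_true(all(ft$wall_band_frac >= 0 & ft$wall_band_frac <= 1))
  expect_true(all(ft$min_dist_mm <= ft$mean_dist_mm))
  # partitions that contain the centerline come arbitrarily close to it
  expect_lt(min(ft$min_dist_mm), max(ph$volume$spacing))

  # single-voxel partition: sd 0, elongation 1
  v <- array(0, c(9, 9, 3)); v[5, 5, 2] <- 50
  vol1 <- image_volume(v, spacing = c(1, 1, 1))
  cl1 <- interpolate_centerline(rbind(c(4.5, 4.5, 0.5), c(4.5, 4.5, 2.5)))
  pm1 <- partition_image(vol1, cl1, k = 2, roi_radius_mm = 20,
                         spatial_weight = 0, seed = 1)
  ft1 <- extract_features(pm1, vol1, lumen_radius_mm = 1)
  one <- which(ft1$n_voxels == 1L)
  expect_length(one, 1L)
  expect_equal(ft1$sd_intensity[one], 0)
  expect_equal(ft1$elongation[one], 1)
})

test_that("a thin shell partition at radius r has mean centerline distance about r", {
  # cylinder shell of radius ~6 around a straight centerline
  n <- 40
  v <- array(0, c(n, n, 10))
  ctr <- (n / 2) * 1 + 0.0
  cl <- interpolate_centerline(rbind(c(ctr, ctr, 1), c(ctr, ctr, 9)))
  xy <- (seq_len(n) - 0.5)
  r2d <- sqrt(outer((xy - ctr)^2, (xy - ctr)^2, "+"))
  shell <- r2d > 5.5 & r2d <= 6.5
  for (k in 2:9) v[, , k] <- shell * 100
  vol <- image_volume(v, spacing = c(1, 1, 1))
  pm <- partition_image(vol, cl, k = 2, roi_radius_mm = 30,
                        spatial_weight = 0, seed = 5)
  ft <- extract_features(pm, vol, lumen_radius_mm = 3)
  bright <- which.max(ft$mean_intensity)
  expect_lt(abs(ft$mean_dist_mm[bright] - 6), 0.75)
})

test_that("manual-mask validation enforces the wall-only convention", {
  ph <- default_phantom()
  cl <- ph$truth$centerline
  r <- ph$truth$lumen_radius_mm
  clean <- validate_manual_mask(ph$truth$wall_mask, ph$volume, cl, r)
  expect_identical(clean$voxels, ph$truth$wall_mask$voxels)

  with_lumen <- seg_mask(ph$truth$wall_mask$voxels |
                           ph$truth$lumen_mask$voxels,
                         ph$volume$spacing, ph$volume$origin)
  expect_error(validate_manual_mask(with_lumen, ph$volume, cl, r),
               "exclude the bowel lumen")

  # a handful of lumen voxels within tolerance are cleaned with a warning
  few <- ph$truth$wall_mask$voxels
  lum_idx <- which(ph$truth$lumen_mask$voxels)
  few[lum_idx[seq_len(5)]] <- TRUE
  expect_warning(
    cleaned <- validate_manual_mask(
      seg_mask(few, ph$volume$spacing, ph$volume$origin),
      ph$volume, cl, r, lumen_overlap_tol = 0.05),
    "removed")
  expect_identical(cleaned$voxels, ph$truth$wall_mask$voxels)

  empty <- seg_mask(array(FALSE, dim(ph$volume$voxels)), ph$volume$spacing)
  expect_error(validate_manual_mask(empty, ph$volume, cl, r), "empty")

  stray <- array(FALSE, dim(ph$volume$voxels)); stray[1, 1, 1] <- TRUE
  expect_error(validate_manual_mask(seg_mask(stray, ph$volume$spacing),
                                    ph$volume, cl, r), "extends")
})

test_that("model training validates inputs and learns degenerate targets", {
  ph <- default_phantom()
  cl <- interpolate_centerline(centerline_from_truth(ph$truth, 10))
  pm <- partition_image(ph$volume, cl, k = 20, seed = 8)
  ft <- extract_features(pm, ph$volume, lumen_radius_mm = 5)

  expect_error(train_partition_model(ft, rep(1, nrow(ft))), "2 distinct")
  expect_error(train_partition_model(list(ft, ft[, -1]),
                                     list(rep(0.5, nrow(ft)),
                                          rep(0.2, nrow(ft)))),
               "schema mismatch")

  tg <- rep(c(0.999, 1), length.out = nrow(ft))
  mod <- train_partition_model(ft, tg, n_trees = 50, seed = 3)
  expect_true(all(predict(mod, ft) > 0.9))
  expect_error(predict(mod, ft[, -2]), "schema")

  mod2 <- train_partition_model(ft, tg, n_trees = 50, seed = 3)
  expect_identical(predict(mod, ft), predict(mod2, ft))
})

test_that("assembly respects probabilities, threshold monotonicity and the lumen ban", {
  ph <- default_phantom()
  truth <- ph$truth
  cl <- interpolate_centerline(centerline_from_truth(truth, 10))
  pm <- partition_image(ph$volume, cl, k = 40, seed = 9)
  frac <- wall_fraction_targets(pm, truth$wall_mask)
  probs <- as.numeric(frac >= 0.5)

  m <- assemble_segmentation(pm, probs, threshold = 0.5,
                             lumen_radius_mm = truth$lumen_radius_mm)
  # oracle probabilities reproduce the union of majority-wall partitions,
  # minus the hard lumen band
  lab <- pm$labels[pm$roi_idx]
  manual_union <- pm$roi_idx[probs[lab] == 1 &
                               pm$dist_mm > truth$lumen_radius_mm]
  expect_setequal(which(m$voxels), manual_union)
  expect_false(any(m$voxels & truth$lumen_mask$voxels))

  counts <- vapply(c(0.2, 0.5, 0.8, 1.0), function(th) {
    sum(assemble_segmentation(pm, frac, threshold = th,
                              lumen_radius_mm = truth$lumen_radius_mm)$voxels)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))

  expect_warning(
    e <- assemble_segmentation(pm, frac, threshold = 1 + 1e-9,
                               lumen_radius_mm = truth$lumen_radius_mm),
    "empty")
  expect_equal(sum(e$voxels), 0)
})

test_that("trained pipeline segments held-out phantoms accurately", {
  mod <- trained_model()
  set.seed(501)
  seeds <- sample.int(2^31 - 2, 4)
  for (s in seeds) {
    ph <- make_phantom(random_phantom_spec(s))
    seg <- semiauto_segment(ph$volume,
                            centerline_from_truth(ph$truth, 10,
                                                  jitter_mm = 1, seed = s),
                            mod, seed = s)
    expect_gte(dice_coefficient(seg$mask, ph$truth$wall_mask), 0.8)
    expect_lte(abs(mask_volume_mL(seg$mask) / ph$truth$true_volume_mL - 1),
               0.15)
    expect_false(any(seg$mask$voxels & ph$truth$lumen_mask$voxels))
  }
})

test_that("manual and semi-automated volumes agree well across a phantom cohort", {
  mod <- trained_model()
  plan <- make_phantom_cohort(n_subjects = 20, rng_seed = 77)
  tab <- measure_phantom_cohort(plan, model = mod, perturb = TRUE,
                                rng_seed = 78)
  res <- icc_agreement(tab$manual_volume_mL, tab$semiauto_volume_mL)
  expect_gte(res$icc, 0.75)
})
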