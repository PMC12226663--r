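#' Validate a manual bowel-wall mask
#'
#' Enforces the wall-only convention on an operator-drawn mask: the mask
#' must exclude the lumen (no more than `lumen_overlap_tol` of its voxels
#' may lie within `lumen_radius_mm` of the centerline — those few are
#' removed; beyond the tolerance the mask is rejected) and must stay
#' within `max_dist_mm` of the centerline (otherwise it cannot be the
#' wall of this bowel segment).
#'
#' @param mask operator [seg_mask()].
#' @param volume the co-registered [image_volume()].
#' @param cl the disease centerline.
#' @param lumen_radius_mm lumen radius, mm (estimate with
#'   [estimate_lumen_radius()] when unknown).
#' @param max_dist_mm maximum allowed distance of any mask voxel from the
#'   centerline, mm.
#' @param lumen_overlap_tol maximum tolerated fraction of mask voxels
#'   inside the lumen.
#' @return The cleaned mask (lumen voxels removed).
#' @export
validate_manual_mask <- function(mask, volume, cl, lumen_radius_mm,
                                 max_dist_mm = 30,
                                 lumen_overlap_tol = 0.02) {
  stopifnot(inherits(mask, "seg_mask"), inherits(volume, "image_volume"),
            inherits(cl, "centerline"))
  if (!same_grid(mask, volume)) {
    stopf("mask is not co-registered with the volume")
  }
  idx <- which(mask$voxels)
  if (!length(idx)) stopf("manual mask is empty")
  centers <- voxel_centers(idx, dim(mask$voxels), mask$spacing, mask$origin)
  d <- dist_to_polyline(centers, cl$points, cl$arc_mm)$dist_mm

  in_lumen <- d <= lumen_radius_mm
  if (mean(in_lumen) > lumen_overlap_tol) {
    stopf(paste0("mask overlaps the lumen (%.1f%% of voxels within ",
                 "%.1f mm of the centerline): wall masks must exclude ",
                 "the bowel lumen, including intraluminal contents"),
          100 * mean(in_lumen), lumen_radius_mm)
  }
  if (any(d > max_dist_mm)) {
    stopf(paste0("mask extends %.1f mm from the centerline (limit ",
                 "%.1f mm): not a wall mask for this segment"),
          max(d), max_dist_mm)
  }
  if (any(in_lumen)) {
    warnf("removed %d mask voxel(s) inside the lumen", sum(in_lumen))
    v <- mask$voxels
    v[idx[in_lumen]] <- FALSE
    mask <- seg_mask(v, mask$spacing, mask$origin)
  }
  mask
}

#' Fraction of each partition inside a reference wall mask
#'
#' Soft training targets for the partition-scoring model: the fraction of
#' a partition's voxels that fall inside the (ground-truth or manual)
#' wall mask.
#'
#' @param pm a [partition_image()] result.
#' @param wall_mask reference [seg_mask()].
#' @return Numeric vector, one value in `[0, 1]` per partition.
#' @export
wall_fraction_targets <- function(pm, wall_mask) {
  stopifnot(inherits(pm, "partition_map"), inherits(wall_mask, "seg_mask"))
  lab <- factor(pm$labels[pm$roi_idx], levels = seq_len(pm$n_partitions))
  as.numeric(tapply(wall_mask$voxels[pm$roi_idx], lab, mean))
}

#' Train the partition-scoring model
#'
#' Fits a random-forest regressor that maps the per-partition feature set
#' to the probability of the partition belonging to the bowel-wall
#' segmentation.  Training targets are soft labels: the fraction of each
#' partition inside a reference wall mask (see
#' [wall_fraction_targets()]).
#'
#' @param feature_tables a [extract_features()] table, or a list of them
#'   (one per training volume); all must share the same feature schema.
#' @param targets numeric vector, or list of vectors co-indexed with
#'   `feature_tables`, of wall fractions in `[0, 1]`.
#' @param n_trees number of trees.
#' @param seed RNG seed; training is deterministic for a fixed seed.
#' @return An object of class `partition_model` with `print()` and
#'   `predict()` methods.  `predict()` refuses feature tables whose
#'   schema differs from the training schema, and clips predictions to
#'   `[0, 1]`.
#' @export
train_partition_model <- function(feature_tables, targets, n_trees = 300L,
                                  seed = 1L) {
  if (is.data.frame(feature_tables)) feature_tables <- list(feature_tables)
  if (is.numeric(targets)) targets <- list(targets)
  if (length(feature_tables) != length(targets)) {
    stopf("need one target vector per feature table")
  }
  schema <- names(feature_tables[[1L]])
  for (ft in feature_tables) {
    if (!identical(names(ft), schema)) {
      stopf("feature schema mismatch across training tables")
    }
  }
  x <- do.call(rbind, lapply(feature_tables, as.data.frame))
  y <- unlist(targets, use.names = FALSE)
  if (nrow(x) != length(y)) stopf("targets are not co-indexed with features")
  if (any(y < 0 | y > 1)) stopf("targets must be wall fractions in [0, 1]")
  if (length(unique(y)) < 2L) {
    stopf("training requires at least 2 distinct target values")
  }
  forest <- with_seed(seed, {
    # Soft wall-fraction targets are often near-binary; randomForest's
    # "five or fewer unique values" regression warning is expected then.
    withCallingHandlers(
      randomForest::randomForest(x = x, y = y, ntree = as.integer(n_trees)),
      warning = function(w) {
        if (grepl("five or fewer unique values", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  })
  structure(list(forest = forest, schema = schema,
                 schema_id = paste(schema, collapse = "|"),
                 n_trees = as.integer(n_trees), seed = as.integer(seed),
                 n_train = nrow(x),
                 version = as.character(utils::packageVersion("enterovol"))),
            class = "partition_model")
}

#' @export
print.partition_model <- function(x, ...) {
  cat(sprintf(paste0("<partition_model> random forest (%d trees) over %d ",
                     "features, trained on %d partitions\n"),
              x$n_trees, length(x$schema), x$n_train))
  invisible(x)
}

#' @param object a `partition_model`.
#' @param newdata a `partition_features` table with the training schema.
#' @param ... unused.
#' @rdname train_partition_model
#' @export
predict.partition_model <- function(object, newdata, ...) {
  if (!identical(names(newdata), object$schema)) {
    stopf("feature schema does not match the model's training schema (%s)",
          object$schema_id)
  }
  p <- predict(object$forest, newdata = as.data.frame(newdata))
  pmin(pmax(as.numeric(p), 0), 1)
}

#' Assemble a wall segmentation from scored partitions
#'
#' Takes the union of partitions whose inclusion probability reaches
#' `threshold` (ties at the threshold are included), removes any voxel
#' inside the lumen band (a hard geometric exclusion around the
#' centerline, enforced regardless of what the model scored), and keeps
#' only face-connected components that touch the expected wall band of
#' the centerline.
#'
#' @param pm a [partition_image()] result.
#' @param probs per-partition inclusion probabilities (vector co-indexed
#'   with partition labels), e.g. from [predict.partition_model()].
#' @param threshold inclusion threshold (default 0.5).
#' @param lumen_radius_mm hard lumen-exclusion radius, mm.
#' @param band_mm a retained component must come within
#'   `lumen_radius_mm + band_mm` of the centerline.
#' @return A [seg_mask()]; empty (with a warning) when nothing passes.
#' @export
assemble_segmentation <- function(pm, probs, threshold = 0.5,
                                  lumen_radius_mm, band_mm = 8) {
  stopifnot(inherits(pm, "partition_map"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stopf("`threshold` must be a positive number")
  }
  check_scalar_pos(lumen_radius_mm, "lumen_radius_mm")
  if (length(probs) != pm$n_partitions) {
    stopf("need one probability per partition (%d)", pm$n_partitions)
  }
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")

  include <- probs >= threshold
  lab <- pm$labels[pm$roi_idx]
  keep <- include[lab] & pm$dist_mm > lumen_radius_mm

  dims <- dim(pm$labels)
  m <- array(FALSE, dims)
  m[pm$roi_idx[keep]] <- TRUE

  if (any(m)) {
    comp <- split_connected(array(as.integer(m), dims), dims)
    comp_roi <- comp[pm$roi_idx]
    touch <- unique(comp_roi[comp_roi > 0L &
                               pm$dist_mm <= lumen_radius_mm + band_mm])
    m <- array(comp %in% touch & comp > 0L, dims)
  }
  if (!any(m)) warnf("assembled segmentation is empty")
  seg_mask(m, pm$spacing, pm$origin)
}

#' Run the full semi-automated segmentation pipeline
#'
#' From operator seed points to a wall mask: interpolate the centerline,
#' estimate the lumen radius (unless given), partition the ROI, extract
#' features, score partitions with a trained [train_partition_model()]
#' model, and assemble the mask.
#'
#' @inheritParams partition_image
#' @param seeds a [seed_points()] set along the lumen.
#' @param model a trained `partition_model`.
#' @param step_mm centerline resampling step, mm.
#' @param lumen_radius_mm lumen radius, mm, or `NULL` to estimate it from
#'   the radial intensity profile.
#' @param wall_band_mm expected wall-band width used by the features and
#'   component retention, mm.
#' @param threshold partition inclusion threshold.
#' @return A list of class `semiauto_segmentation`: `mask`, `centerline`,
#'   `partitions`, `features`, `probs`, `lumen_radius_mm`.
#' @export
semiauto_segment <- function(volume, seeds, model, k = 40,
                             roi_radius_mm = 15, spatial_weight = 0.5,
                             threshold = 0.5, lumen_radius_mm = NULL,
                             wall_band_mm = 6, step_mm = 0.5, seed = 1L) {
  stopifnot(inherits(model, "partition_model"))
  cl <- if (inherits(seeds, "centerline")) seeds else
    interpolate_centerline(seeds, step_mm = step_mm)
  if (is.null(lumen_radius_mm)) {
    lumen_radius_mm <- estimate_lumen_radius(volume, cl)
  }
  pm <- partition_image(volume, cl, k = k, roi_radius_mm = roi_radius_mm,
                        spatial_weight = spatial_weight, seed = seed)
  ft <- extract_features(pm, volume, lumen_radius_mm = lumen_radius_mm,
                         wall_band_mm = wall_band_mm)
  probs <- predict(model, ft)
  mask <- assemble_segmentation(pm, probs, threshold = threshold,
                                lumen_radius_mm = lumen_radius_mm,
                                band_mm = wall_band_mm + 2)
  structure(list(mask = mask, centerline = cl, partitions = pm,
                 features = ft, probs = probs,
                 lumen_radius_mm = lumen_radius_mm),
            class = "semiauto_segmentation")
}

#' @export
print.semiauto_segmentation <- function(x, ...) {
  cat(sprintf(paste0("<semiauto_segmentation> %d/%d partitions included; ",
                     "volume %.1f mL; lumen radius %.1f mm\n"),
              sum(x$probs >= 0.5), x$partitions$n_partitions,
              mask_volume_mL(x$mask), x$lumen_radius_mm))
  invisible(x)
}

#' Train a partition model on randomly drawn phantoms
#'
#' Convenience trainer for the semi-automated segmenter: draws
#' `n_phantoms` random phantoms ([random_phantom_spec()]), runs the
#' partition + feature stage on each with an operator-like centerline
#' (10 jittered seeds), and fits the scoring forest against the
#' ground-truth wall fractions.
#'
#' @param n_phantoms number of training phantoms (default 30).
#' @param rng_seed master seed; per-phantom seeds are drawn from it.
#' @param k,roi_radius_mm,spatial_weight,wall_band_mm passed to the
#'   partition/feature stage.
#' @param n_trees forest size.
#' @param ... passed to [random_phantom_spec()] (grid, noise, ranges).
#' @return A [train_partition_model()] model.
#' @export
train_on_phantoms <- function(n_phantoms = 30, rng_seed = 1L, k = 40,
                              roi_radius_mm = 15, spatial_weight = 0.5,
                              wall_band_mm = 6, n_trees = 300L, ...) {
  seeds <- with_seed(rng_seed, sample.int(2^31 - 2, n_phantoms + 1L))
  fts <- vector("list", n_phantoms)
  tgs <- vector("list", n_phantoms)
  for (i in seq_len(n_phantoms)) {
    ph <- make_phantom(random_phantom_spec(seeds[i], ...))
    cl <- interpolate_centerline(
      centerline_from_truth(ph$truth, 10L, jitter_mm = 1, seed = seeds[i]))
    lum <- estimate_lumen_radius(ph$volume, cl)
    pm <- partition_image(ph$volume, cl, k = k,
                          roi_radius_mm = roi_radius_mm,
                          spatial_weight = spatial_weight, seed = seeds[i])
    fts[[i]] <- extract_features(pm, ph$volume, lumen_radius_mm = lum,
                                 wall_band_mm = wall_band_mm)
    tgs[[i]] <- wall_fraction_targets(pm, ph$truth$wall_mask)
  }
  train_partition_model(fts, tgs, n_trees = n_trees,
                        seed = seeds[n_phantoms + 1L])
}
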