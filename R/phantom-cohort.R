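#' Draw a random phantom specification
#'
#' Samples a plausible inflamed-ileum phantom: lumen radius, wall
#' thickness, segment length and in-plane undulation drawn uniformly from
#' the given ranges, with the bowel path running through the slice stack.
#' Used to build training and held-out sets for the semi-automated
#' segmenter.
#'
#' @param seed integer seed (also the phantom's noise seed).
#' @param grid_shape,spacing grid geometry, as in [phantom_spec()].
#' @param lumen_range,wall_range min/max of lumen radius and wall
#'   thickness, mm.
#' @param noise_sigma noise sd, intensity units.
#' @return A [phantom_spec()].
#' @export
random_phantom_spec <- function(seed, grid_shape = c(72L, 72L, 30L),
                                spacing = c(1.3, 1.3, 5.0),
                                lumen_range = c(3.5, 6),
                                wall_range = c(2.5, 6),
                                noise_sigma = 8) {
  with_seed(seed, {
    lum <- runif(1, lumen_range[1L], lumen_range[2L])
    wall <- runif(1, wall_range[1L], wall_range[2L])
    span <- runif(1, 0.55, 0.75)
    amp <- runif(1, 0.06, 0.13)
    phase <- runif(1, 0, 2 * pi)
    phantom_spec(grid_shape = grid_shape, spacing = spacing,
                 curve_control_points = undulating_path(
                   grid_shape * spacing, span, amp, phase),
                 lumen_radius_mm = lum, wall_thickness_mm = wall,
                 noise_sigma = noise_sigma, rng_seed = seed)
  })
}

undulating_path <- function(extent, span, amp, phase, scale = 1) {
  mid <- extent[3L] / 2
  z <- seq(mid - scale * span * extent[3L] / 2,
           mid + scale * span * extent[3L] / 2, length.out = 7L)
  fr <- (z - z[1L]) / (z[length(z)] - z[1L])
  cbind(extent[1L] / 2 + scale * amp * extent[1L] * sin(2 * pi * fr + phase),
        extent[2L] / 2 + scale * amp * extent[2L] * cos(1.5 * pi * fr + phase),
        z)
}

#' Simulate a longitudinal phantom cohort with treatment response
#'
#' Builds per-subject, per-timepoint phantom specifications in which the
#' inflamed segment responds to therapy multiplicatively: wall thickness
#' and segment length (path extent) shrink by per-timepoint factors,
#' emulating diagnosis / 6-week / 6-month imaging.  Subjects vary in
#' baseline lumen radius, wall thickness and segment length.
#'
#' @param n_subjects number of subjects.
#' @param wall_shrink,length_shrink multiplicative factors in `(0, 1]`
#'   per timepoint (baseline first).  Defaults mirror the study-scale
#'   declines of the linear measurements.
#' @param grid_shape,spacing,noise_sigma phantom geometry and noise.
#' @param rng_seed master seed; each phantom gets its own derived seed.
#' @return A data.frame of class `phantom_cohort_plan` with columns
#'   `subject_id`, `timepoint`, `seed`, and the geometric parameters; use
#'   [measure_phantom_cohort()] to generate and measure the phantoms.
#' @export
make_phantom_cohort <- function(n_subjects = 20,
                                wall_shrink = c(1, 0.76, 0.59),
                                length_shrink = c(1, 0.64, 0.42),
                                grid_shape = c(72L, 72L, 30L),
                                spacing = c(1.3, 1.3, 5.0),
                                noise_sigma = 8, rng_seed = 1L) {
  if (n_subjects < 2) stopf("`n_subjects` must be at least 2")
  if (any(wall_shrink <= 0 | wall_shrink > 1) ||
      any(length_shrink <= 0 | length_shrink > 1)) {
    stopf("shrink factors must lie in (0, 1]")
  }
  with_seed(rng_seed, {
    plan <- expand.grid(timepoint = timepoint_levels(),
                        subject_id = sprintf("S%02d", seq_len(n_subjects)),
                        stringsAsFactors = FALSE)[, 2:1]
    ns <- nrow(plan)
    tp <- match(plan$timepoint, timepoint_levels())
    lum <- runif(n_subjects, 3.5, 6)
    wall <- runif(n_subjects, 3, 6)
    span <- runif(n_subjects, 0.55, 0.75)
    amp <- runif(n_subjects, 0.06, 0.13)
    phase <- runif(n_subjects, 0, 2 * pi)
    si <- match(plan$subject_id, sprintf("S%02d", seq_len(n_subjects)))
    plan$seed <- sample.int(2^31 - 2, ns)
    plan$lumen_radius_mm <- lum[si]
    plan$wall_thickness_mm <- wall[si] * wall_shrink[tp]
    plan$span <- span[si] * length_shrink[tp]
    plan$amp <- amp[si] * length_shrink[tp]
    plan$phase <- phase[si]
    attr(plan, "grid_shape") <- grid_shape
    attr(plan, "spacing") <- spacing
    attr(plan, "noise_sigma") <- noise_sigma
    class(plan) <- c("phantom_cohort_plan", "data.frame")
    plan
  })
}

# Materialize one row of a phantom cohort plan into a phantom_spec.
plan_spec <- function(plan, i) {
  gs <- attr(plan, "grid_shape"); sp <- attr(plan, "spacing")
  phantom_spec(grid_shape = gs, spacing = sp,
               curve_control_points = undulating_path(
                 gs * sp, plan$span[i], plan$amp[i], plan$phase[i]),
               lumen_radius_mm = plan$lumen_radius_mm[i],
               wall_thickness_mm = plan$wall_thickness_mm[i],
               noise_sigma = attr(plan, "noise_sigma"),
               rng_seed = plan$seed[i])
}

#' Perturb a mask like an imperfect human operator
#'
#' Emulates manual-segmentation variability: per examination a bias is
#' drawn in `(-strength, strength)` and the mask boundary is dilated
#' (positive bias: each background voxel face-adjacent to the mask is
#' added with that probability) or eroded (negative bias: each boundary
#' mask voxel removed), giving exam-level volume errors of a few percent
#' with subject ranking preserved.
#'
#' @param mask a [seg_mask()].
#' @param strength maximum flip probability (default 0.3).
#' @param seed RNG seed.
#' @return A perturbed [seg_mask()].
#' @export
perturb_mask <- function(mask, strength = 0.3, seed = NULL) {
  stopifnot(inherits(mask, "seg_mask"))
  if (strength < 0 || strength > 1) stopf("`strength` must be in [0, 1]")
  with_seed(seed, {
    q <- runif(1, -strength, strength)
    v <- mask$voxels
    dims <- dim(v)
    lab <- array(as.integer(v), dims)
    if (q >= 0) {
      cand <- which(adjacent_to(lab, dims) & !v)
      v[cand[runif(length(cand)) < q]] <- TRUE
    } else {
      cand <- which(boundary_voxels(lab, dims))
      v[cand[runif(length(cand)) < -q]] <- FALSE
    }
    seg_mask(v, mask$spacing, mask$origin)
  })
}

# Background voxels with at least one 6-neighbor inside the mask.
adjacent_to <- function(lab, dims) {
  out <- array(FALSE, dims)
  strides <- c(1L, dims[1L], dims[1L] * dims[2L])
  for (ax in 1:3) {
    keep <- slot_mask(dims, ax)
    a <- which(keep)
    b <- a + strides[ax]
    out[a[lab[a] == 0L & lab[b] > 0L]] <- TRUE
    out[b[lab[b] == 0L & lab[a] > 0L]] <- TRUE
  }
  out
}

#' Generate and measure a phantom cohort
#'
#' Materializes each phantom of a [make_phantom_cohort()] plan and
#' measures it with the package's own pipeline: length of disease from
#' operator-like seeds on the true centerline, "manual" volume and wall
#' thicknesses from the (optionally operator-perturbed) ground-truth wall
#' mask, and, when a trained model is supplied, the semi-automated volume
#' from [semiauto_segment()].
#'
#' @param plan a `phantom_cohort_plan`.
#' @param model optional [train_partition_model()] model; without it the
#'   `semiauto_volume_mL` column is omitted.
#' @param n_seeds operator seed points per examination.
#' @param perturb logical; perturb the truth mask with [perturb_mask()]
#'   before "manual" measurement.
#' @param rng_seed master seed for seed placement and perturbation.
#' @return A longitudinal table (see [as_longitudinal_table()]).
#' @export
measure_phantom_cohort <- function(plan, model = NULL, n_seeds = 10,
                                   perturb = TRUE, rng_seed = 1L) {
  stopifnot(inherits(plan, "phantom_cohort_plan"))
  sub_seeds <- with_seed(rng_seed, sample.int(2^31 - 2, nrow(plan)))
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    ph <- make_phantom(plan_spec(plan, i))
    cl <- interpolate_centerline(
      centerline_from_truth(ph$truth, n_seeds, jitter_mm = 1,
                            seed = sub_seeds[i]))
    man <- if (perturb) {
      perturb_mask(ph$truth$wall_mask, seed = sub_seeds[i] %% 2^30 + 1L)
    } else {
      ph$truth$wall_mask
    }
    prof <- thickness_profile(man)
    rec <- data.frame(subject_id = plan$subject_id[i],
                      timepoint = plan$timepoint[i],
                      max_thickness_mm = attr(prof, "max_mm"),
                      mean_thickness_mm = attr(prof, "mean_mm"),
                      length_cm = centerline_length(cl),
                      manual_volume_mL = mask_volume_mL(man))
    if (!is.null(model)) {
      seg <- semiauto_segment(ph$volume, cl, model,
                              seed = sub_seeds[i] %% 2^29 + 1L)
      rec$semiauto_volume_mL <- mask_volume_mL(seg$mask)
    }
    rec
  })
  as_longitudinal_table(do.call(rbind, rows))
}
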