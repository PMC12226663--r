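#' Interpolate a centerline through seed points
#'
#' Builds the curved line a reading radiologist obtains by clicking seed
#' points along the affected bowel lumen: a natural cubic interpolating
#' spline on a chord-length parameterization, passing through every seed,
#' densely resampled at (at most) `step_mm` arc-length intervals.  Its
#' total arc length is the "length of disease".
#'
#' @param seeds a [seed_points()] object (or n-by-3 mm matrix).
#' @param step_mm resampling resolution along the curve, mm.  The default
#'   0.5 mm is well below in-plane voxel spacing, so resampling error is
#'   negligible against seed-placement error.
#' @return An object of class `centerline`: list with `points` (m-by-3 mm),
#'   `arc_mm` (nondecreasing cumulative arc length, `arc_mm[1] == 0`), and
#'   `seed_idx` (row indices of the original seeds within `points`).
#' @details Exact consecutive duplicate seeds are collapsed (with a
#'   warning); if all seeds coincide the centerline is rejected.
#' @export
interpolate_centerline <- function(seeds, step_mm = 0.5) {
  if (!inherits(seeds, "seed_points")) seeds <- seed_points(seeds)
  check_scalar_pos(step_mm, "step_mm")
  pts <- unclass(seeds)

  dup <- c(FALSE, rowSums(abs(diff(pts))) == 0)
  if (any(dup)) {
    warnf("collapsed %d duplicate consecutive seed point(s)", sum(dup))
    pts <- pts[!dup, , drop = FALSE]
  }
  if (nrow(pts) < 2L) stopf("all seed points coincide; cannot interpolate")

  fine <- densify_curve(pts, fine_step_mm = step_mm / 4)
  total <- fine$arc_mm[length(fine$arc_mm)]

  # Arc-length grid, augmented with the seeds' own positions so the
  # resampled polyline passes through every seed exactly.
  seed_arc <- cumulative_arc(pts)              # chord-length approximation
  seed_arc <- vapply(seq_len(nrow(pts)), function(i) {
    d <- fine$points - matrix(pts[i, ], nrow(fine$points), 3, byrow = TRUE)
    fine$arc_mm[which.min(rowSums(d * d))]
  }, numeric(1))
  grid <- sort(unique(c(seq(0, total, by = step_mm), total, seed_arc)))
  out <- resample_polyline(fine$points, fine$arc_mm, grid)
  # Snap the seed rows onto the exact seed coordinates.
  seed_idx <- vapply(seed_arc, function(a) which.min(abs(grid - a)),
                     integer(1))
  out[seed_idx, ] <- pts

  structure(list(points = out, arc_mm = cumulative_arc(out),
                 seed_idx = seed_idx, step_mm = step_mm),
            class = "centerline")
}

#' Length of disease along a centerline
#'
#' @param cl a `centerline`.
#' @param digits decimal places for reporting, or `NULL` (default) for the
#'   full-precision value.  Reports use 0.1 cm resolution.
#' @return Arc length in cm.
#' @export
centerline_length <- function(cl, digits = NULL) {
  stopifnot(inherits(cl, "centerline"))
  len <- cl$arc_mm[length(cl$arc_mm)] / 10
  if (is.null(digits)) len else round(len, digits)
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, length of disease %.1f cm\n",
              nrow(x$points), centerline_length(x)))
  invisible(x)
}

#' Simulate operator seed placement on a phantom's true centerline
#'
#' Samples `n_seeds` points at equal arc-length spacing along the true
#' bowel path of a phantom, optionally jittered to emulate imprecise
#' clicks.  Jitter is isotropic and must stay within the lumen radius
#' (clicks land in the lumen).
#'
#' @param truth a `phantom_truth` object from [make_phantom()].
#' @param n_seeds number of seeds (>= 2).
#' @param jitter_mm sd-free uniform jitter half-width per axis, mm; must
#'   not exceed the phantom lumen radius.
#' @param seed RNG seed for the jitter.
#' @return A [seed_points()] object.
#' @export
centerline_from_truth <- function(truth, n_seeds, jitter_mm = 0,
                                  seed = NULL) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (n_seeds < 2L) stopf("`n_seeds` must be at least 2")
  if (jitter_mm < 0) stopf("`jitter_mm` must be nonnegative")
  if (jitter_mm > truth$lumen_radius_mm) {
    stopf("jitter (%.2f mm) exceeds the lumen radius (%.2f mm)",
          jitter_mm, truth$lumen_radius_mm)
  }
  cl <- truth$centerline
  total <- cl$arc_mm[length(cl$arc_mm)]
  pts <- resample_polyline(cl$points, cl$arc_mm,
                           seq(0, total, length.out = n_seeds))
  if (jitter_mm > 0) {
    pts <- pts + with_seed(seed, {
      matrix(runif(length(pts), -jitter_mm, jitter_mm), nrow(pts), 3L)
    })
  }
  seed_points(pts)
}

#' Write a centerline as a JSON polyline
#'
#' @param cl a `centerline`.
#' @param path output `.json` path.
#' @export
write_centerline <- function(cl, path) {
  stopifnot(inherits(cl, "centerline"))
  m <- cl$points
  dimnames(m) <- NULL
  jsonlite::write_json(
    list(points = m, arc_mm = cl$arc_mm,
         length_cm = centerline_length(cl, digits = 1)),
    path, digits = NA)
  invisible(path)
}
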