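
# Natural cubic interpolating spline through ordered 3D points on a
# chord-length parameterization, evaluated at parameter values tt.
spline_eval <- function(points, t_knots, tt) {
  cbind(splinefun(t_knots, points[, 1L], method = "natural")(tt),
        splinefun(t_knots, points[, 2L], method = "natural")(tt),
        splinefun(t_knots, points[, 3L], method = "natural")(tt))
}

chord_lengths <- function(points) {
  d <- diff(points)
  sqrt(rowSums(d * d))
}

cumulative_arc <- function(points) {
  c(0, cumsum(chord_lengths(points)))
}

# Densify a control polygon into a fine polyline along the interpolating
# spline. Returns points + cumulative arc length. fine_step_mm controls the
# parameter sampling used to approximate arc length.
densify_curve <- function(control, fine_step_mm) {
  control <- as.matrix(control)
  if (nrow(control) == 2L) {
    # Two points define a straight segment.
    n <- max(2L, ceiling(sum(chord_lengths(control)) / fine_step_mm) + 1L)
    tt <- seq(0, 1, length.out = n)
    pts <- outer(1 - tt, control[1L, ]) + outer(tt, control[2L, ])
    return(list(points = pts, arc_mm = cumulative_arc(pts)))
  }
  t_knots <- cumulative_arc(control)
  total <- t_knots[length(t_knots)]
  n <- max(4L, ceiling(total / fine_step_mm) + 1L)
  tt <- seq(0, total, length.out = n)
  pts <- spline_eval(control, t_knots, tt)
  list(points = pts, arc_mm = cumulative_arc(pts))
}

# Resample a fine polyline at the given target arc-length positions by
# linear interpolation between fine vertices.
resample_polyline <- function(points, arc_mm, targets) {
  targets <- pmin(pmax(targets, 0), arc_mm[length(arc_mm)])
  cbind(approx(arc_mm, points[, 1L], xout = targets, ties = "ordered")$y,
        approx(arc_mm, points[, 2L], xout = targets, ties = "ordered")$y,
        approx(arc_mm, points[, 3L], xout = targets, ties = "ordered")$y)
}

# Minimum distance (mm) from each row of pts to a dense polyline, and the
# arc-length position of the nearest vertex. Thin wrapper over the
# compiled kernel.
dist_to_polyline <- function(pts, curve_points, curve_arc_mm = NULL) {
  pts <- as.matrix(pts)
  curve_points <- as.matrix(curve_points)
  if (is.null(curve_arc_mm)) curve_arc_mm <- cumulative_arc(curve_points)
  storage.mode(pts) <- "double"
  storage.mode(curve_points) <- "double"
  .dist_to_polyline_cpp(pts, curve_points, as.numeric(curve_arc_mm))
}
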