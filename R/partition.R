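#' Partition a volume around a centerline into contiguous regions
#'
#' First stage of the semi-automated segmenter: voxels within
#' `roi_radius_mm` of the centerline are clustered by k-means on
#' (intensity, spatially weighted physical coordinates), and every
#' cluster is then split into face-connected (6-connectivity) components
#' so that each final partition is one contiguous region — a
#' superpixel-like decomposition whose granularity is set by `k` and the
#' compactness trade-off by `spatial_weight`.
#'
#' @param volume an [image_volume()].
#' @param cl a [interpolate_centerline()] centerline through the lumen.
#' @param k number of k-means clusters (>= 1; default 40 gives partitions
#'   smaller than wall structures but large enough for stable partition
#'   statistics).
#' @param roi_radius_mm region-of-interest radius around the centerline,
#'   mm.
#' @param spatial_weight relative weight of spatial coordinates against
#'   intensity in the clustering space (0 = intensity only; default 0.5).
#'   Coordinates are scaled by the expected partition diameter
#'   `(ROI volume / k)^(1/3)`, intensity by its ROI standard deviation.
#' @param seed RNG seed for k-means initialization; partitioning is
#'   deterministic for a fixed seed.
#' @return An object of class `partition_map`: `labels` (3D integer grid,
#'   0 outside the ROI), `n_partitions`, and cached per-ROI-voxel
#'   geometry (`roi_idx`, `dist_mm`, `arc_mm`) reused by
#'   [extract_features()] and [assemble_segmentation()].
#' @export
partition_image <- function(volume, cl, k = 40, roi_radius_mm = 15,
                            spatial_weight = 0.5, seed = 1L) {
  stopifnot(inherits(volume, "image_volume"), inherits(cl, "centerline"))
  if (!is.numeric(k) || k < 1) stopf("`k` must be at least 1")
  k <- as.integer(k)
  check_scalar_pos(roi_radius_mm, "roi_radius_mm")
  if (spatial_weight < 0) stopf("`spatial_weight` must be nonnegative")

  dims <- dim(volume$voxels)
  centers <- voxel_centers(seq_len(prod(dims)), dims, volume$spacing,
                           volume$origin)
  dres <- dist_to_polyline(centers, cl$points, cl$arc_mm)
  roi <- which(dres$dist_mm <= roi_radius_mm)
  if (length(roi) == 0L) stopf("ROI is empty: no voxel within %.1f mm of the centerline",
                               roi_radius_mm)
  if (k > length(roi)) {
    stopf("k = %d exceeds the ROI size (%d voxels)", k, length(roi))
  }

  ints <- volume$voxels[roi]
  s_int <- sd(ints)
  if (s_int == 0) s_int <- 1
  feat <- cbind((ints - mean(ints)) / s_int)
  if (spatial_weight > 0) {
    cell <- (length(roi) * prod(volume$spacing) / k)^(1 / 3)
    feat <- cbind(feat, spatial_weight * centers[roi, , drop = FALSE] / cell)
  }

  km_cluster <- if (k == 1L) {
    rep(1L, length(roi))
  } else {
    with_seed(seed, kmeans(feat, centers = k, iter.max = 100L,
                           nstart = 1L)$cluster)
  }

  clab <- array(0L, dims)
  clab[roi] <- km_cluster
  labels <- split_connected(clab, dims)

  structure(list(labels = labels, n_partitions = max(labels),
                 roi_idx = roi, dist_mm = dres$dist_mm[roi],
                 arc_mm = dres$arc_mm[roi],
                 spacing = volume$spacing, origin = volume$origin,
                 k = k, roi_radius_mm = roi_radius_mm,
                 spatial_weight = spatial_weight, seed = seed),
            class = "partition_map")
}

#' @export
print.partition_map <- function(x, ...) {
  cat(sprintf("<partition_map> %d contiguous partitions over %d ROI voxels (k = %d)\n",
              x$n_partitions, length(x$roi_idx), x$k))
  invisible(x)
}

# Relabel a cluster-label array so every nonzero label is one
# face-connected (6-connectivity) component.  Adjacency graph built over
# same-cluster voxel pairs along the three axes; components via igraph.
split_connected <- function(clab, dims) {
  roi <- which(clab > 0L)
  pos <- integer(length(clab))
  pos[roi] <- seq_along(roi)

  edges <- vector("list", 3L)
  strides <- c(1L, dims[1L], dims[1L] * dims[2L])
  for (ax in 1:3) {
    keep <- slot_mask(dims, ax)          # voxels with an in-grid +1 neighbor
    a <- which(keep & clab > 0L)
    b <- a + strides[ax]
    ok <- clab[b] == clab[a] & clab[b] > 0L
    edges[[ax]] <- cbind(pos[a[ok]], pos[b[ok]])
  }
  e <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(roi), directed = FALSE)
  if (nrow(e) > 0L) g <- igraph::add_edges(g, t(e))
  memb <- igraph::components(g)$membership

  out <- array(0L, dims)
  out[roi] <- as.integer(memb)
  out
}

# Logical array marking voxels whose +1 neighbor along `ax` is in-grid.
slot_mask <- function(dims, ax) {
  idx <- slice.index(array(0L, dims), ax)
  idx < dims[ax]
}

#' Per-partition feature table
#'
#' Characterizes each partition with the custom feature set consumed by
#' the partition-scoring model: intensity statistics, size, shape, and
#' centerline-relative geometry.
#'
#' @param pm a [partition_image()] result.
#' @param volume the co-registered [image_volume()].
#' @param lumen_radius_mm lumen radius used for the wall-band feature
#'   (the annulus `lumen_radius < d <= lumen_radius + wall_band_mm`
#'   around the centerline where bowel wall is expected); estimate it
#'   with [estimate_lumen_radius()] when unknown.
#' @param wall_band_mm width of the expected wall band, mm.
#' @return A data.frame of class `partition_features`, one row per
#'   partition (row order = partition label), with columns `n_voxels`,
#'   `volume_mm3`, `mean_intensity`, `sd_intensity`, `min_dist_mm`,
#'   `mean_dist_mm`, `elongation`, `boundary_gradient`, `wall_band_frac`.
#' @export
extract_features <- function(pm, volume, lumen_radius_mm, wall_band_mm = 6) {
  stopifnot(inherits(pm, "partition_map"), inherits(volume, "image_volume"))
  check_scalar_pos(lumen_radius_mm, "lumen_radius_mm")
  check_scalar_pos(wall_band_mm, "wall_band_mm")
  dims <- dim(volume$voxels)
  lab <- pm$labels[pm$roi_idx]
  stopifnot(all(lab > 0L))
  P <- pm$n_partitions
  f <- factor(lab, levels = seq_len(P))

  ints <- volume$voxels[pm$roi_idx]
  n_vox <- as.integer(table(f))
  stopifnot(all(n_vox > 0L))
  mean_int <- as.numeric(tapply(ints, f, mean))
  sd_int <- as.numeric(tapply(ints, f, function(v) if (length(v) > 1L) sd(v) else 0))
  min_d <- as.numeric(tapply(pm$dist_mm, f, min))
  mean_d <- as.numeric(tapply(pm$dist_mm, f, mean))
  in_band <- pm$dist_mm > lumen_radius_mm &
    pm$dist_mm <= lumen_radius_mm + wall_band_mm
  band_frac <- as.numeric(tapply(in_band, f, mean))

  centers <- voxel_centers(pm$roi_idx, dims, volume$spacing, volume$origin)
  elong <- vapply(split(seq_along(lab), f), function(ix) {
    if (length(ix) < 3L) return(1)
    ev <- eigen(stats::cov(centers[ix, , drop = FALSE]),
                symmetric = TRUE, only.values = TRUE)$values
    eps <- mean(volume$spacing)^2 / 12   # single-voxel extent floor
    sqrt((max(ev) + eps) / (max(min(ev), 0) + eps))
  }, numeric(1))

  grad <- gradient_magnitude(volume)
  on_boundary <- boundary_voxels(pm$labels, dims)
  bg <- rep(NA_real_, P)
  bidx <- pm$roi_idx[on_boundary[pm$roi_idx]]
  if (length(bidx)) {
    bf <- factor(pm$labels[bidx], levels = seq_len(P))
    bg <- as.numeric(tapply(grad[bidx], bf, mean))
  }
  bg[is.na(bg)] <- as.numeric(tapply(grad[pm$roi_idx], f, mean))[is.na(bg)]

  out <- data.frame(n_voxels = n_vox,
                    volume_mm3 = n_vox * prod(volume$spacing),
                    mean_intensity = mean_int, sd_intensity = sd_int,
                    min_dist_mm = min_d, mean_dist_mm = mean_d,
                    elongation = unname(elong), boundary_gradient = bg,
                    wall_band_frac = band_frac)
  stopifnot(all(is.finite(as.matrix(out))))
  class(out) <- c("partition_features", "data.frame")
  out
}

# Central-difference gradient magnitude in physical units (per mm).
gradient_magnitude <- function(volume) {
  v <- volume$voxels
  dims <- dim(v)
  g2 <- array(0, dims)
  for (ax in 1:3) {
    d <- array(0, dims)
    n <- dims[ax]
    if (n >= 2L) {
      fwd <- shift_diff(v, ax)
      d <- fwd / volume$spacing[ax]
    }
    g2 <- g2 + d^2
  }
  sqrt(g2)
}

# Symmetric difference along one axis (one-sided at the ends), divided by
# 2 in the interior.
shift_diff <- function(v, ax) {
  dims <- dim(v)
  n <- dims[ax]
  idx_lo <- pmax(seq_len(n) - 1L, 1L)
  idx_hi <- pmin(seq_len(n) + 1L, n)
  hi <- index_axis(v, ax, idx_hi)
  lo <- index_axis(v, ax, idx_lo)
  (hi - lo) / pmax(idx_hi - idx_lo, 1L)
}

index_axis <- function(v, ax, idx) {
  switch(ax,
         v[idx, , , drop = FALSE],
         v[, idx, , drop = FALSE],
         v[, , idx, drop = FALSE])
}

# Voxels with at least one 6-neighbor carrying a different label
# (grid edges count as boundary for labeled voxels).
boundary_voxels <- function(labels, dims) {
  out <- array(FALSE, dims)
  strides <- c(1L, dims[1L], dims[1L] * dims[2L])
  for (ax in 1:3) {
    keep <- slot_mask(dims, ax)
    a <- which(keep)
    b <- a + strides[ax]
    diffpair <- labels[a] != labels[b]
    out[a[diffpair]] <- TRUE
    out[b[diffpair]] <- TRUE
    edge <- slice.index(array(0L, dims), ax)
    out[edge == 1L | edge == dims[ax]] <- out[edge == 1L | edge == dims[ax]] |
      labels[edge == 1L | edge == dims[ax]] > 0L
  }
  out & labels > 0L
}

#' Estimate the lumen radius from the radial intensity profile
#'
#' On bright-lumen T2-weighted images the mean intensity as a function of
#' distance to the centerline drops from the fluid plateau to wall/
#' background level at the lumen boundary; the estimate is the half-way
#' crossing of that radial profile.
#'
#' @param volume an [image_volume()].
#' @param cl the lumen centerline.
#' @param max_radius_mm how far out to profile, mm.
#' @param bin_mm radial bin width, mm.
#' @return Estimated lumen radius, mm.
#' @export
estimate_lumen_radius <- function(volume, cl, max_radius_mm = 12,
                                  bin_mm = 0.5) {
  stopifnot(inherits(volume, "image_volume"), inherits(cl, "centerline"))
  dims <- dim(volume$voxels)
  centers <- voxel_centers(seq_len(prod(dims)), dims, volume$spacing,
                           volume$origin)
  d <- dist_to_polyline(centers, cl$points, cl$arc_mm)$dist_mm
  sel <- d <= max_radius_mm
  bins <- floor(d[sel] / bin_mm)
  prof <- as.numeric(tapply(volume$voxels[sel], bins, mean))
  mids <- (sort(unique(bins)) + 0.5) * bin_mm
  lumen_level <- mean(prof[mids <= max(2, 2 * bin_mm)])
  floor_level <- min(prof)
  thr <- (lumen_level + floor_level) / 2
  below <- which(prof < thr)
  if (!length(below) || below[1L] == 1L) {
    stopf("no lumen plateau found: is the centerline inside the lumen?")
  }
  # The lumen boundary is the steepest descent of the radial profile
  # within its bright part (partial volume smears the halfway crossing
  # outward into the wall; the inflection is nearly unbiased).
  high <- which(prof >= thr)
  high <- high[high < length(prof)]
  drops <- -diff(prof)
  j <- high[which.max(drops[high])]
  (mids[j] + mids[j + 1L]) / 2
}
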