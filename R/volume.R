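#' Construct a 3D image volume
#'
#' The common substrate of the pipeline: a 3D grayscale intensity grid on
#' an axis-aligned physical grid with (possibly anisotropic) voxel spacing
#' in millimetres.  Voxel `(i, j, k)` (0-based) has its center at
#' `origin + (c(i, j, k) + 0.5) * spacing`.
#'
#' @param voxels 3D numeric array of intensities.
#' @param spacing numeric length-3, mm per voxel along each axis; strictly
#'   positive.  The default mimics a coronal single-shot fast spin-echo
#'   acquisition: 1.3 mm in-plane, 5 mm through-plane.
#' @param origin numeric length-3, physical mm offset of the grid corner.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing = c(1.3, 1.3, 5.0),
                         origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stopf("`voxels` must be a 3D array (got %s dimension(s))",
          length(dim(voxels)))
  }
  if (any(dim(voxels) < 1L)) stopf("`voxels` must be nonempty")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    stopf("`spacing` must be 3 strictly positive mm values")
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L || !all(is.finite(origin))) {
    stopf("`origin` must be 3 finite mm values")
  }
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Construct a binary segmentation mask
#'
#' A mask is co-registered with its parent volume (same grid, spacing and
#' origin) and is strictly binary.  Bowel-wall masks follow the wall-only
#' convention: serosa to mucosa, lumen and intraluminal contents excluded.
#'
#' @param voxels 3D array coercible to logical.
#' @inheritParams image_volume
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(voxels, spacing = c(1.3, 1.3, 5.0), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stopf("mask `voxels` must be a 3D array")
  }
  if (is.numeric(voxels) && !all(voxels %in% c(0, 1))) {
    stopf("mask voxels must be binary (0/1)")
  }
  v <- array(as.logical(voxels), dim(voxels))
  if (anyNA(v)) stopf("mask voxels must not contain NA")
  obj <- image_volume(array(0, dim(v)), spacing, origin)
  structure(list(voxels = v, spacing = obj$spacing, origin = obj$origin),
            class = "seg_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm\n",
              paste(dim(x$voxels), collapse = " x "),
              paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask> %s voxels, spacing %s mm, %d foreground (%.2f mL)\n",
              paste(dim(x$voxels), collapse = " x "),
              paste(format(x$spacing), collapse = " x "),
              sum(x$voxels), mask_volume_mL(x)))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Read / write NIfTI-1 volumes
#'
#' Volumes and masks are exchanged as NIfTI-1 files with voxel spacing in
#' the header (`pixdim`).  The round trip preserves voxel values and
#' spacing exactly.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param mask logical; read the file as a binary [seg_mask()] (values are
#'   checked to be 0/1) rather than an [image_volume()].
#' @return `read_volume()` returns an `image_volume` (or `seg_mask`);
#'   `write_volume()` returns `path` invisibly.
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stopf("no such NIfTI file: %s", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stopf("cannot read NIfTI %s: %s",
                                            path, conditionMessage(e)))
  a <- as.array(img)
  if (length(dim(a)) != 3L) {
    stopf("%s holds a %dD image; a 3D volume is required",
          path, length(dim(a)))
  }
  sp <- RNifti::pixdim(img)[seq_len(3L)]
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    stopf("%s has implausible voxel spacing (%s)", path,
          paste(sp, collapse = ", "))
  }
  # pixdim is float32 in the NIfTI-1 header; snapping to 7 significant
  # digits recovers the decimal mm spacing that was written.
  sp <- signif(sp, 7L)
  a <- array(as.numeric(a), dim(a))
  if (mask) seg_mask(a, spacing = sp) else image_volume(a, spacing = sp)
}

#' @param vol an `image_volume` or `seg_mask`.
#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, c("image_volume", "seg_mask")))
  v <- vol$voxels
  if (is.logical(v)) v <- array(as.integer(v), dim(v))
  img <- RNifti::asNifti(v)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an ordered seed-point set
#'
#' Seed points are the operator's clicks along the affected intestinal
#' lumen, ordered from one end of the diseased segment to the other, in
#' physical mm coordinates.  Supported formats: JSON (an array of
#' `[x, y, z]` triples, optionally under a `"points"` key) and CSV with
#' columns `x`, `y`, `z`.
#'
#' @param path JSON or CSV file.
#' @return An object of class `seed_points`: a numeric n-by-3 matrix.
#' @export
read_seeds <- function(path) {
  if (!file.exists(path)) stopf("no such seed file: %s", path)
  ext <- tolower(tools::file_ext(path))
  pts <- if (ext == "json") {
    x <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
    if (is.list(x) && !is.null(x$points)) x <- x$points
    as.matrix(x)
  } else if (ext == "csv") {
    x <- read.csv(path)
    if (!all(c("x", "y", "z") %in% names(x))) {
      stopf("seed CSV must have columns x, y, z")
    }
    as.matrix(x[, c("x", "y", "z")])
  } else {
    stopf("unsupported seed format: .%s (use .json or .csv)", ext)
  }
  seed_points(pts)
}

#' @param points numeric n-by-3 matrix of mm coordinates, n >= 2.
#' @rdname read_seeds
#' @export
seed_points <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stopf("seed points must be n x 3 (x, y, z in mm)")
  if (nrow(points) < 2L) {
    stopf("at least 2 seed points are required to build a centerline")
  }
  if (!all(is.finite(points))) stopf("seed coordinates must be finite")
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(points, class = c("seed_points", "matrix", "array"))
}

#' Write seed points as JSON
#'
#' @param seeds a `seed_points` object.
#' @param path output `.json` path.
#' @export
write_seeds <- function(seeds, path) {
  stopifnot(inherits(seeds, "seed_points"))
  m <- unclass(seeds)
  dimnames(m) <- NULL
  jsonlite::write_json(list(points = m), path, digits = NA)
  invisible(path)
}
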