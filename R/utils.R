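
# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stopf("`%s` must be a single positive finite number", name)
  }
  invisible(x)
}

# Linear voxel index -> physical mm coordinates of voxel centers.
# Convention shared by every module: axis-aligned grid, 0-based voxel
# index i has its center at origin + (i + 0.5) * spacing; in R's 1-based
# indexing that is origin + (i - 0.5) * spacing.
voxel_centers <- function(idx, dim, spacing, origin = c(0, 0, 0)) {
  idx <- as.integer(idx) - 1L
  i <- idx %% dim[1L]
  j <- (idx %/% dim[1L]) %% dim[2L]
  k <- idx %/% (dim[1L] * dim[2L])
  cbind(origin[1L] + (i + 0.5) * spacing[1L],
        origin[2L] + (j + 0.5) * spacing[2L],
        origin[3L] + (k + 0.5) * spacing[3L])
}
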