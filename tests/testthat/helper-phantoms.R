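# Shared fixtures, built in code.  Expensive objects (the trained
# partition model) are cached for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

# Straight tube along the slice axis: the analytically simplest phantom.
straight_tube_spec <- function(wall = 3, lumen = 5, noise = 0,
                               grid = c(64L, 64L, 28L), length_mm = 100,
                               seed = 1L) {
  z0 <- (grid[3L] * 5 - length_mm) / 2
  phantom_spec(grid_shape = grid, spacing = c(1.3, 1.3, 5.0),
               curve_control_points = cbind(40, 40, c(z0, z0 + length_mm)),
               lumen_radius_mm = lumen, wall_thickness_mm = wall,
               noise_sigma = noise, rng_seed = seed)
}

# Partition model trained on 30 random phantoms (the study-scale training
# set); built once per test run.
trained_model <- function() {
  if (is.null(.fixture_cache$model)) {
    .fixture_cache$model <- train_on_phantoms(n_phantoms = 30, rng_seed = 2024)
  }
  .fixture_cache$model
}

# A default noisy phantom, cached.
default_phantom <- function() {
  if (is.null(.fixture_cache$phantom)) {
    .fixture_cache$phantom <- make_phantom(phantom_spec())
  }
  .fixture_cache$phantom
}

# Ten (baseline, follow-up) group-mean pairs as printed for the study
# cohort, with their reported integer percent declines.
printed_percent_changes <- function() {
  data.frame(
    measurement = rep(c("max_thickness_mm", "length_cm",
                        "manual_volume_mL", "semiauto_volume_mL",
                        "mean_thickness_mm"), each = 2),
    baseline = rep(c(7.6, 19.2, 19.8, 24.0, 3.6), each = 2),
    followup = c(5.8, 4.5, 12.2, 8.0, 11.6, 5.1, 15.1, 9.1, 3.3, 2.6),
    expected = c(24, 41, 36, 58, 41, 74, 37, 62, 8, 28))
}
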