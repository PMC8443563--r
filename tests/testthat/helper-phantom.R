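# small, fast phantom configurations shared across tests

small_sphere_spec <- function(delta_n = 0.01, grid = 96, px = 0.17, ...) {
  phantom_spec(nucleus_semi_axes = c(5, 5, 5), nucleus_delta_n = delta_n,
               nucleolus_semi_axes = NULL, grid_shape = c(grid, grid),
               pixel_size = px, angle_schedule = 0, ...)
}

small_triaxial_spec <- function(angles = schedule_uniform(26, 300),
                                grid = 128, px = 0.25, ...) {
  phantom_spec(grid_shape = c(grid, grid), pixel_size = px,
               angle_schedule = angles, ...)
}

# a minor-axis curve with four extrema of which the first and last are
# global and the middle two are local: the nucleus rotates uniformly but the
# frames straddle (rather than hit) the 180- and 270-degree extremes, so the
# sampled curve turns without reaching the global min/max there
four_extrema_angles <- function() {
  c(60, 75, 90, 108, 126, 144, 162, 198, 216, 234, 252, 288,
    306, 324, 342, 360, 372, 384)
}

four_extrema_curve <- function(b = 7, c_ = 3.5, L = 23.44) {
  th <- four_extrema_angles()
  build_minor_axis_curve(tibble::tibble(
    minor_len = ellipsoid_minor_axis(th, b, c_),
    major_len = L))
}

# minor-axis extent of the support of a rendered projection (um):
# vertical extent of the above-threshold region, measured through the centre
measure_minor_support <- function(phase, pixel_size, thr = 1e-6) {
  rows <- which(apply(phase > thr, 1, any))
  (max(rows) - min(rows) + 1) * pixel_size
}
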