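test_that("analytic projections match closed forms", {
  # sphere: chord at centre is the diameter, at any rolling angle
  sp <- small_sphere_spec()
  sp$angle_schedule <- c(0, 57.3)
  pf <- make_phantom(sp)
  peak_expected <- 2 * pi / 0.532 * 0.01 * 10
  expect_equal(max(pf$phase_maps[[1]]$phase), peak_expected, tolerance = 1e-3)
  expect_equal(pf$phase_maps[[1]]$phase, pf$phase_maps[[2]]$phase)

  # triaxial, axis-aligned: projections expose 2b and 2c
  tp <- small_triaxial_spec(angles = c(0, 45, 90), px = 0.17, grid = 160)
  tp$nucleolus_semi_axes <- NULL
  pf <- make_phantom(tp)
  expect_equal(measure_minor_support(pf$phase_maps[[1]]$phase, 0.17), 14.0,
               tolerance = 0.17 * 2 / 14)
  expect_equal(measure_minor_support(pf$phase_maps[[3]]$phase, 0.17), 7.0,
               tolerance = 0.17 * 2 / 7)
  # 45 degrees: l = 2*sqrt((b^2 + c^2)/2), within 1 px of the support
  l45 <- 2 * sqrt((7^2 + 3.5^2) / 2)
  expect_equal(measure_minor_support(pf$phase_maps[[2]]$phase, 0.17), l45,
               tolerance = 0.17 / l45)
})

test_that("projected area and integrated phase behave under rotation", {
  sp <- small_triaxial_spec(angles = c(0, 30, 60, 90, 180, 210),
                            grid = 160, px = 0.25)
  pf <- make_phantom(sp)
  px2 <- sp$pixel_size^2
  a <- sp$nucleus_semi_axes[1]; b <- sp$nucleus_semi_axes[2]
  c_ <- sp$nucleus_semi_axes[3]
  for (i in seq_along(sp$angle_schedule)) {
    beta <- sp$angle_schedule[i] * pi / 180
    area_true <- pi * a * sqrt(b^2 * cos(beta)^2 + c_^2 * sin(beta)^2)
    area_meas <- sum(pf$phase_maps[[i]]$phase > 1e-9) * px2
    expect_equal(area_meas, area_true, tolerance = 0.02)
  }
  # area has period 180 degrees
  area_of <- function(i) sum(pf$phase_maps[[i]]$phase > 1e-9)
  expect_equal(area_of(1), area_of(5))  # 0 vs 180
  expect_equal(area_of(2), area_of(6))  # 30 vs 210
  # mass conservation: integral of phi equals (2 pi / lambda) * sum(dn * V)
  mass_true <- 2 * pi / sp$wavelength *
    (sp$nucleus_delta_n * pf$truth_volume_nucleus +
       sp$nucleolus_delta_n * pf$truth_volume_nucleolus)
  for (i in seq_along(sp$angle_schedule)) {
    expect_equal(sum(pf$phase_maps[[i]]$phase) * px2, mass_true,
                 tolerance = 0.01)
  }
})

test_that("voxel-summation renderer agrees with the analytic chord renderer", {
  sp <- small_triaxial_spec(angles = 37, grid = 120, px = 0.3)
  a <- render_phantom_frame(sp, 37)
  v <- render_phantom_frame_voxel(sp, 37, z_step = 0.1)
  expect_lt(sqrt(mean((a - v)^2)), 0.02 * max(a))
})

test_that("spec validation, clipping and seeded noise", {
  # clipped: nucleus does not fit in the frame
  expect_error(make_phantom(small_triaxial_spec(grid = 64, px = 0.17)),
               "clipped")
  # nucleolus must lie inside the nucleus
  expect_error(phantom_spec(nucleolus_center_offset = c(10, 0, 0)),
               "inside")
  expect_error(phantom_spec(nucleus_semi_axes = c(3, 7, 5)), "a >= b >= c")
  expect_error(phantom_spec(noise_sigma_phase = -1), "noise")
  # same seed gives bit-identical frames
  s1 <- small_triaxial_spec(angles = c(0, 40), noise_sigma_phase = 0.05,
                            seed = 42)
  expect_identical(make_phantom(s1)$phase_maps, make_phantom(s1)$phase_maps)
  s2 <- small_triaxial_spec(angles = c(0, 40), noise_sigma_phase = 0.05,
                            seed = 43)
  expect_false(identical(make_phantom(s1)$phase_maps[[1]]$phase,
                         make_phantom(s2)$phase_maps[[1]]$phase))
})

test_that("hologram synthesis: fringe structure and contracts", {
  q <- phase_map(matrix(0, 64, 64), 0.17, 0.532)
  h <- synthesize_hologram(q, carrier_freq = c(0.25, 0), ref_amp = 1,
                           obj_amp = 1)
  expect_true(all(h$intensity >= 0))
  expect_equal(range(h$intensity), c(0, 4), tolerance = 1e-10)
  # period-4 fringes along x: every 4th column equal
  expect_equal(h$intensity[1, 1:60], h$intensity[1, 5:64])
  expect_gt(stats::sd(h$intensity[1, 1:4]), 0.5)
  # mean intensity = ref^2 + obj^2 over whole carrier periods
  h2 <- synthesize_hologram(q, c(0.25, 0.125), ref_amp = 2, obj_amp = 1)
  expect_equal(mean(h2$intensity), 2^2 + 1^2, tolerance = 1e-10)
  expect_error(synthesize_hologram(q, c(0.5, 0)), "Nyquist")
  expect_error(synthesize_hologram(q, c(0.25, 0), ref_amp = 0), "amplitude")
})
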