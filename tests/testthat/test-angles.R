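test_that("ellipsoid minor-axis projection matches the closed form and a numeric projection", {
  expect_equal(ellipsoid_minor_axis(0, 7, 3.5), 14)
  expect_equal(ellipsoid_minor_axis(90, 7, 3.5), 7)
  expect_equal(ellipsoid_minor_axis(45, 7, 3.5), 2 * sqrt((49 + 12.25) / 2))
  expect_equal(ellipsoid_minor_axis(60, 7, 3.5),
               2 * sqrt(49 * 0.25 + 12.25 * 0.75))
  # numeric projection support agrees within one pixel
  sp <- small_triaxial_spec(angles = c(20, 45, 60, 75), grid = 160,
                            px = 0.17)
  sp$nucleolus_semi_axes <- NULL
  pf <- make_phantom(sp)
  for (i in seq_along(sp$angle_schedule)) {
    l_num <- measure_minor_support(pf$phase_maps[[i]]$phase, 0.17)
    l_ana <- ellipsoid_minor_axis(sp$angle_schedule[i], 7, 3.5)
    expect_lt(abs(l_num - l_ana), 0.17 * 1.5)
  }
})

test_that("angle inversion is exact, monotone, and guards its domain", {
  expect_equal(invert_angle(14, 7, 3.5), 0)
  expect_equal(invert_angle(7, 7, 3.5), 90)
  expect_equal(invert_angle(2 * sqrt((49 + 12.25) / 2), 7, 3.5), 45)
  ls <- seq(7, 14, length.out = 50)
  expect_true(all(diff(invert_angle(ls, 7, 3.5)) < 0))
  # round trip through the forward model
  betas <- seq(0, 90, by = 5)
  expect_equal(invert_angle(ellipsoid_minor_axis(betas, 7, 3.5), 7, 3.5),
               betas, tolerance = 1e-9)
  # slight excursions are clipped with a warning, larger ones error
  expect_warning(b <- invert_angle(14.05, 7, 3.5, clip_tol = 0.17), "clip")
  expect_equal(b, 0)
  expect_error(invert_angle(14.5, 7, 3.5, clip_tol = 0.17), "interval")
  expect_error(invert_angle(10, 5, 5), "unobservable")
})

test_that("elliptic segmentation reproduces the phantom geometry", {
  sp <- small_triaxial_spec(angles = c(0, 37), grid = 216, px = 0.17)
  pf <- make_phantom(sp)
  seg <- segment_ellipse(pf$phase_maps[[1]])
  # major axis 2a = 23.44 um, minor 2b = 14 um, within 2 px
  expect_equal(seg$ellipse$major_len, 23.44, tolerance = 0.34 / 23.44)
  expect_equal(seg$ellipse$minor_len, 14.0, tolerance = 0.34 / 14)
  expect_equal(seg$ellipse$tilt_deg, 0, tolerance = 1)
  expect_false(seg$ellipse$circular)
  expect_true(is.matrix(seg$mask))
  expect_error(segment_ellipse(phase_map(matrix(0, 50, 50), 0.17, 0.532)),
               "not found")
  # near-circular projection (a ~ b at beta = 0) flagged
  spc <- phantom_spec(nucleus_semi_axes = c(5, 4.9, 3),
                      nucleolus_semi_axes = NULL, grid_shape = c(160, 160),
                      pixel_size = 0.17, angle_schedule = 0)
  segc <- segment_ellipse(make_phantom(spc)$phase_maps[[1]])
  expect_true(segc$ellipse$circular)
})

test_that("align_and_center puts the major axis along x at the frame centre", {
  sp <- small_triaxial_spec(angles = 25, grid = 216, px = 0.17)
  pf <- make_phantom(sp)
  q <- pf$phase_maps[[1]]
  # rotate the scene in-plane by 37 degrees and shift it off-centre
  ny <- 216
  xs <- seq_len(ny) - (ny + 1) / 2
  th <- 37 * pi / 180
  src_r <- outer(xs, rep(1, ny)) * cos(th) - outer(rep(1, ny), xs) * sin(th)
  src_c <- outer(xs, rep(1, ny)) * sin(th) + outer(rep(1, ny), xs) * cos(th)
  rot <- matrix(
    holotomo:::bilinear_sample(q$phase, c(src_r + (ny - 1) / 2 + 6),
                               c(src_c + (ny - 1) / 2 - 9)), ny, ny)
  qrot <- phase_map(rot, 0.17, 0.532)
  seg <- segment_ellipse(qrot)
  expect_equal(abs(seg$ellipse$tilt_deg), 37, tolerance = 1.5 / 37)
  ali <- align_and_center(qrot, seg$ellipse)
  # aligned map matches the original (already axis-aligned, centred) frame
  seg2 <- segment_ellipse(ali)
  expect_equal(seg2$ellipse$tilt_deg, 0, tolerance = 1)
  expect_equal(seg2$ellipse$cx, (ny - 1) / 2 * 0.17, tolerance = 0.17)
  expect_equal(seg2$ellipse$cy, (ny - 1) / 2 * 0.17, tolerance = 0.17)
  core <- abs(q$phase) > 0.3
  expect_lt(sqrt(mean((ali$phase - q$phase)[core]^2)), 0.12)
  # aligning an already-aligned frame is the identity up to interpolation
  seg0 <- segment_ellipse(q)
  ali0 <- align_and_center(q, seg0$ellipse, mask_background = FALSE)
  expect_lt(max(abs(ali0$phase - q$phase)[core]), 0.05)
})

test_that("minor-axis curve finds and classifies extrema", {
  # uniformly sampled fold: all extrema global, at multiples of 90 degrees
  th <- seq(10, 710, by = 20)
  cur <- build_minor_axis_curve(
    tibble::tibble(minor_len = ellipsoid_minor_axis(th, 7, 3.5),
                   major_len = 23.44))
  ext <- attr(cur, "extrema")
  expect_true(all(ext$kind %in% c("global_min", "global_max")))
  # extrema within half a frame step of a multiple of 90 degrees (frames
  # straddling an extreme symmetrically record it at the earlier frame)
  dist90 <- pmin(th[ext$frame] %% 90, 90 - th[ext$frame] %% 90)
  expect_true(all(dist90 <= 10))
  # alternating sides
  expect_true(all(ext$side[-1] != ext$side[-nrow(ext)]))
  # four-extrema curve: global, local, local, global
  cur4 <- four_extrema_curve()
  ext4 <- attr(cur4, "extrema")
  expect_equal(ext4$kind,
               c("global_min", "local", "local", "global_max"))
  # monotone curve: no extremes, unwrap refuses
  mono <- build_minor_axis_curve(
    tibble::tibble(minor_len = ellipsoid_minor_axis(seq(5, 85, 10), 7, 3.5)))
  expect_equal(nrow(attr(mono, "extrema")), 0)
  expect_error(unwrap_angles(mono), "insufficient rotation")
})

test_that("unwrapping accumulates 90 degrees per extreme and excludes local extremes", {
  cur <- four_extrema_curve()
  ang <- unwrap_angles(cur)
  ext <- attr(ang, "extrema")
  # exactly 90 degrees between successive extremes, 270 between the globals
  expect_equal(diff(ext$theta_nominal), rep(90, 3))
  glob <- ext$theta_nominal[ext$kind != "local"]
  expect_equal(diff(glob), 270)
  # the two local-extreme frames are invalid, all others valid
  expect_equal(sum(!ang$valid), 2)
  expect_equal(ang$frame[!ang$valid], ext$frame[ext$kind == "local"])
  # theta non-decreasing and correct against the generating schedule
  expect_true(all(diff(ang$theta_deg) >= 0))
  th <- four_extrema_angles()
  truth <- th - th[1] + ang$theta_deg[1]
  expect_lt(max(abs(ang$theta_deg - truth)[ang$valid]), 1e-6)
})

test_that("a single-extreme 130-degree roll keeps every frame valid and continuous", {
  # rotation from 48 to 178 degrees crosses only the 90-degree minimum
  th <- seq(48, 178, by = 5)
  cur <- build_minor_axis_curve(
    tibble::tibble(minor_len = ellipsoid_minor_axis(th, 7, 3.5)))
  ext <- attr(cur, "extrema")
  expect_equal(nrow(ext), 1)
  ang <- unwrap_angles(cur)
  expect_true(all(ang$valid))
  expect_equal(attr(ang, "max_rolling_angle"), 130, tolerance = 0.03)
  # no discontinuity: increments stay near the 5-degree frame step
  expect_lt(max(diff(ang$theta_deg)), 15)
})

test_that("rolling angles are recovered from rendered phantom sequences", {
  sp <- small_triaxial_spec(angles = schedule_uniform(26, 300))
  pf <- make_phantom(sp)
  rec <- recover_rolling_angles(pf$phase_maps)
  ang <- rec$angles
  truth <- pf$truth$angle_deg
  err <- ang$theta_deg - (truth - truth[1] + ang$theta_deg[1])
  expect_lt(sqrt(mean(err[ang$valid]^2)), 2.5)
  expect_equal(attr(ang, "max_rolling_angle"), 300, tolerance = 0.02)
  # major-axis constancy holds for a rigid single-axis rotation
  expect_true(check_major_axis_constancy(
    dplyr::bind_rows(rec$ellipses)$major_len))
  expect_warning(check_major_axis_constancy(c(20, 20, 26, 20)), "violated")
})

test_that("random phantoms with noise recover angles within tolerance", {
  set.seed(101)
  rmse <- vapply(1:5, function(i) {
    bc <- runif(1, 1.3, 3)
    c_semi <- runif(1, 2.5, 3.5)
    span <- runif(1, 200, 330)
    sp <- phantom_spec(
      nucleus_semi_axes = c(11, bc * c_semi, c_semi),
      nucleolus_semi_axes = NULL, grid_shape = c(110, 110),
      pixel_size = 0.3, noise_sigma_phase = 0.05, seed = 1000 + i,
      angle_schedule = schedule_uniform(24, span, start = runif(1, 0, 80)))
    pf <- make_phantom(sp)
    rec <- suppressWarnings(recover_rolling_angles(pf$phase_maps))
    ang <- rec$angles
    truth <- pf$truth$angle_deg
    err <- ang$theta_deg - (truth - truth[1] + ang$theta_deg[1])
    sqrt(mean(err[ang$valid]^2))
  }, numeric(1))
  expect_lt(median(rmse), 3)
})
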