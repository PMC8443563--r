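test_that("demodulation recovers constant and smooth phases", {
  # constant phase, carrier on exact frequency bins
  qc <- phase_map(matrix(0.7, 64, 64), 0.17, 0.532)
  f <- demodulate_offaxis(synthesize_hologram(qc, c(0.25, 0.125)))
  ph <- field_phase(f)$phase[9:56, 9:56]
  expect_lt(max(abs(ph - median(ph))), 1e-3)
  # smooth Gaussian phase
  xs <- (seq_len(96) - 48.5) * 0.17
  g <- outer(xs, xs, function(y, x) 1.5 * exp(-(x^2 + y^2) / 12))
  qs <- phase_map(g, 0.17, 0.532)
  f2 <- demodulate_offaxis(synthesize_hologram(qs, c(0.25, 0.125)))
  e <- (field_phase(f2)$phase - g)[17:80, 17:80]
  e <- e - median(e)
  expect_lt(sqrt(mean(e^2)), 1e-2)
})

test_that("demodulated phantom sphere matches the analytic projection", {
  sp <- small_sphere_spec()
  q <- make_phantom(sp)$phase_maps[[1]]
  f <- demodulate_offaxis(synthesize_hologram(q, c(0.25, 0.25)))
  ph <- field_phase(f)$phase
  int <- 17:80
  err <- (ph - q$phase)[int, int]
  err <- err - median(err)
  # the ideal sphere rim is a gradient discontinuity and not band-limited;
  # compare away from it
  xs <- (seq_len(96) - 48.5) * 0.17
  R <- sqrt(outer(xs^2, xs^2, "+"))[int, int]
  expect_lt(sqrt(mean(err[abs(R - 5) > 0.6]^2)), 1e-2)
})

test_that("carrier detection fails cleanly", {
  q <- phase_map(matrix(0.3, 64, 64), 0.17, 0.532)
  h <- synthesize_hologram(q, c(0.25, 0))
  h_bad <- hologram(h$intensity, h$pixel_size, h$wavelength,
                    carrier_hint = c(0.05, 0))  # off by > window width
  expect_error(demodulate_offaxis(h_bad), "carrier")
  # no carrier at all
  flat <- hologram(matrix(1, 64, 64), 0.17, 0.532)
  expect_error(demodulate_offaxis(flat), "no carrier")
})

test_that("angular-spectrum propagation is unitary and invertible", {
  # band-limited field: smooth Gaussian phase object passed once through the
  # propagating band (a tiny step zeroes the evanescent tail exactly)
  xs <- (seq_len(96) - 48.5) * 0.17
  g <- outer(xs, xs, function(y, x) 1.2 * exp(-(x^2 + y^2) / 10))
  raw <- complex_field(exp(1i * g), 0.17, 0.532)
  expect_identical(propagate(raw, 0), raw)
  fld <- propagate(raw, 1e-9)
  p1 <- propagate(fld, 25)
  expect_equal(sum(Mod(p1$values)^2), sum(Mod(fld$values)^2),
               tolerance = 1e-6)
  p2 <- propagate(p1, -25)
  expect_lt(max(Mod(p2$values - fld$values)), 1e-9)
})

test_that("propagated Gaussian beam follows the analytic width law", {
  n <- 256; px <- 0.4; lam <- 0.532
  xs <- (seq_len(n) - (n + 1) / 2) * px
  w0 <- 6
  U <- outer(xs, xs, function(y, x) exp(-(x^2 + y^2) / w0^2))
  fld <- complex_field(U + 0i, px, lam)
  zr <- pi * w0^2 / lam
  for (z in c(0.5, 1, 1.5) * zr) {
    w_true <- w0 * sqrt(1 + (z / zr)^2)
    I <- Mod(propagate(fld, z)$values)^2
    # second-moment width of the intensity profile: <x^2> = w^2 / 4
    wx <- 2 * sqrt(sum(I * outer(rep(1, n), xs^2)) / sum(I))
    expect_equal(wx, w_true, tolerance = 0.02)
  }
})

test_that("tamura coefficient matches hand computations", {
  expect_equal(tamura(matrix(3, 5, 5)), 0)
  expect_equal(tamura(c(1, 3)), sqrt(1 / 2))  # population sd 1, mean 2
  expect_error(tamura(matrix(0, 3, 3)), "positive")
  # contrast stretch beats blur
  set.seed(1)
  img <- matrix(runif(64^2), 64)
  blurred <- EBImage::gblur(img, sigma = 3)
  expect_gt(tamura(img), tamura(blurred))
})

test_that("autofocus recovers numerically applied defocus", {
  sp <- small_sphere_spec()
  q <- make_phantom(sp)$phase_maps[[1]]
  fld <- complex_field(exp(1i * q$phase), 0.17, 0.532)
  # search step is 90/18 = 5 um; recovery within one refinement step.
  # (ranges stay comparable to the frame extent: periodic propagation makes
  # far larger defocus distances unphysical on a small frame)
  zf <- autofocus(propagate(fld, 30), c(-45, 45), n_steps = 19)
  expect_equal(as.numeric(zf), -30, tolerance = 5 / 30)
  # already focused
  zf0 <- autofocus(fld, c(-40, 40), n_steps = 17)
  expect_lt(abs(as.numeric(zf0)), 5)
  # property: random defocus values, max error below 2 grid steps
  set.seed(7)
  dzs <- runif(10, -35, 35)
  step <- 90 / 18
  errs <- vapply(dzs, function(dz) {
    zf <- suppressWarnings(autofocus(propagate(fld, dz), c(-45, 45),
                                     n_steps = 19))
    abs(as.numeric(zf) + dz)
  }, numeric(1))
  expect_lt(max(errs), 2 * step)
  # featureless plane wave: warning path
  pw <- complex_field(matrix(1 + 0i, 64, 64), 0.17, 0.532)
  expect_warning(autofocus(pw, c(-20, 20), n_steps = 5), "unimodal")
})

test_that("least-squares unwrapping restores smooth multi-radian phase", {
  xs <- (seq_len(80) - 40.5)
  g <- outer(xs, xs, function(x, y) 8 * exp(-(x^2 + y^2) / 300))
  wrapped <- atan2(sin(g), cos(g))
  expect_gt(max(g), pi)  # genuinely wrapped input
  expect_lt(max(abs(unwrap_phase(wrapped) - g)), 1e-9)
})
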