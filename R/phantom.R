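#' Specification of a rotating two-ellipsoid nucleus phantom
#'
#' Defines the ground-truth scene used to exercise the whole pipeline: a rigid
#' triaxial ellipsoid "nucleus" of uniform refractive-index contrast over the
#' cytoplasmic background, containing a smaller, denser ellipsoid "nucleolus",
#' rotating about its major axis which lies in the image plane (the x axis).
#'
#' Default geometry mirrors the segmented nucleus the angle-tracking worked
#' example is built around: major axis L = 23.44 um (a = 11.72 um) and minor
#' semi-axes b = 7, c = 3.5 um, nucleoplasm contrast 0.022 over a cytoplasm
#' background of 1.368, nucleolus a further 0.02 above the nucleoplasm.
#'
#' @param nucleus_semi_axes Length-3 numeric, semi-axes (a, b, c) in um with
#'   a >= b >= c > 0. a lies along the rotation axis x, b along y, c along z
#'   at rolling angle 0.
#' @param nucleus_delta_n Refractive-index contrast of nucleoplasm over the
#'   background (dimensionless).
#' @param nucleolus_semi_axes Length-3 numeric (um), or NULL for no nucleolus.
#' @param nucleolus_center_offset Length-3 offset (um) of the nucleolus centre
#'   in the nucleus body frame.
#' @param nucleolus_delta_n Additional contrast of the nucleolus over the
#'   nucleoplasm.
#' @param background_ri Background refractive index (cytoplasm; default 1.368).
#' @param wavelength Illumination wavelength (um; default 0.532).
#' @param pixel_size Image-plane pixel size (um; default 0.17).
#' @param grid_shape Length-2 integer (ny, nx) pixels.
#' @param angle_schedule Numeric vector of true rolling angles (degrees), one
#'   per frame; see [schedule_uniform()] and [schedule_sinusoidal()].
#' @param noise_sigma_phase Standard deviation of i.i.d. Gaussian phase noise
#'   (radians) added to each rendered frame.
#' @param seed Integer seed used for the noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(nucleus_semi_axes = c(11.72, 7, 3.5),
                         nucleus_delta_n = 0.022,
                         nucleolus_semi_axes = c(2.5, 2.2, 2.0),
                         nucleolus_center_offset = c(0, 0, 0),
                         nucleolus_delta_n = 0.02,
                         background_ri = 1.368,
                         wavelength = 0.532,
                         pixel_size = 0.17,
                         grid_shape = c(216, 216),
                         angle_schedule = schedule_uniform(26, span = 300),
                         noise_sigma_phase = 0,
                         seed = 1L) {
  s <- nucleus_semi_axes
  if (length(s) != 3 || any(!is.finite(s)) || any(s <= 0))
    abort("nucleus_semi_axes must be 3 positive numbers")
  if (!(s[1] >= s[2] && s[2] >= s[3]))
    abort("nucleus semi-axes must satisfy a >= b >= c")
  if (!is.null(nucleolus_semi_axes)) {
    if (length(nucleolus_semi_axes) != 3 || any(nucleolus_semi_axes <= 0))
      abort("nucleolus_semi_axes must be 3 positive numbers")
    if (!ellipsoid_inside(nucleolus_semi_axes, nucleolus_center_offset, s))
      abort("nucleolus ellipsoid is not entirely inside the nucleus")
  }
  if (any(!is.finite(angle_schedule))) abort("angle_schedule must be finite")
  if (noise_sigma_phase < 0) abort("noise_sigma_phase must be >= 0")
  if (length(grid_shape) != 2 || any(grid_shape < 8))
    abort("grid_shape must be (ny, nx), both >= 8")
  structure(
    list(nucleus_semi_axes = s, nucleus_delta_n = nucleus_delta_n,
         nucleolus_semi_axes = nucleolus_semi_axes,
         nucleolus_center_offset = nucleolus_center_offset,
         nucleolus_delta_n = nucleolus_delta_n,
         background_ri = background_ri, wavelength = wavelength,
         pixel_size = pixel_size, grid_shape = as.integer(grid_shape),
         angle_schedule = angle_schedule,
         noise_sigma_phase = noise_sigma_phase, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# analytic containment check: ellipsoid (semi, centred at offset, co-aligned)
# inside unit-scaled ellipsoid with semi-axes outer. Maximizes
# Q(u) = sum_i ((d_i + s_i u_i)/S_i)^2 over the unit sphere |u| = 1
# (coarse spherical grid + local refinement).
ellipsoid_inside <- function(semi, offset, outer) {
  qfun <- function(th, ph) {
    u <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    sum(((offset + semi * u) / outer)^2)
  }
  th <- seq(0, pi, length.out = 31)
  ph <- seq(0, 2 * pi, length.out = 61)
  g <- outer(th, ph, Vectorize(qfun))
  best <- which(g == max(g), arr.ind = TRUE)[1, ]
  opt <- stats::optim(c(th[best[1]], ph[best[2]]),
                      function(p) -qfun(p[1], p[2]),
                      method = "Nelder-Mead")
  -opt$value <= 1
}

#' Uniform rolling-angle schedule
#'
#' @param n_frames Number of frames.
#' @param span Total rotation covered (degrees).
#' @param start Angle of the first frame (degrees).
#' @return Numeric vector of angles (degrees).
#' @export
schedule_uniform <- function(n_frames, span = 300, start = 0) {
  seq(start, start + span, length.out = n_frames)
}

#' Sinusoidally modulated rolling-angle schedule
#'
#' Non-uniform angular velocity: the rotation rate oscillates around the mean,
#' so sampled minor-axis curves acquire unevenly spaced extrema, some of which
#' fall between frames and show up only as local (non-global) extrema --
#' the situation the angle unwrapping must label and exclude.
#'
#' @inheritParams schedule_uniform
#' @param depth Relative modulation depth in (0, 1).
#' @param cycles Number of velocity oscillations over the sequence.
#' @return Numeric vector of angles (degrees).
#' @export
schedule_sinusoidal <- function(n_frames, span = 300, start = 0,
                                depth = 0.6, cycles = 2) {
  stopifnot(depth > 0, depth < 1)
  u <- seq(0, 1, length.out = n_frames)
  ang <- u + depth * sin(2 * pi * cycles * u) / (2 * pi * cycles)
  start + span * (ang - ang[1]) / (ang[n_frames] - ang[1])
}

# quadratic-form matrix of an ellipsoid with semi-axes `semi` (body frame
# a->x, b->y, c->z) rotated by beta degrees about +x
ellipsoid_quadric <- function(semi, beta_deg) {
  b <- beta_deg * pi / 180
  R <- matrix(c(1, 0, 0,
                0, cos(b), sin(b),
                0, -sin(b), cos(b)), 3, 3)  # columns are images of body axes
  D <- diag(1 / semi^2)
  R %*% D %*% t(R)
}

# chord lengths along lab z of the rotated ellipsoid at lab (x, y), centre at
# lab-frame `centre` (length 3). x, y are equal-length vectors.
ellipsoid_chord <- function(x, y, semi, beta_deg, centre = c(0, 0, 0)) {
  M <- ellipsoid_quadric(semi, beta_deg)
  xr <- x - centre[1]; yr <- y - centre[2]
  # z measured relative to centre z: shift absorbed since chord is invariant
  A <- M[3, 3]
  B <- 2 * (M[1, 3] * xr + M[2, 3] * yr)
  C <- M[1, 1] * xr^2 + 2 * M[1, 2] * xr * yr + M[2, 2] * yr^2 - 1
  disc <- B^2 - 4 * A * C
  out <- numeric(length(x))
  pos <- disc > 0
  out[pos] <- sqrt(disc[pos]) / A
  out
}

# rotate a body-frame point by beta degrees about +x into the lab frame
rotate_x <- function(p, beta_deg) {
  b <- beta_deg * pi / 180
  c(p[1], cos(b) * p[2] - sin(b) * p[3], sin(b) * p[2] + cos(b) * p[3])
}

# analytic phase projection of the two-ellipsoid model at one rolling angle
render_phantom_frame <- function(spec, beta_deg) {
  ny <- spec$grid_shape[1]; nx <- spec$grid_shape[2]
  xs <- axis_coords(nx, spec$pixel_size)
  ys <- axis_coords(ny, spec$pixel_size)
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)
  k <- 2 * pi / spec$wavelength
  chord_n <- ellipsoid_chord(c(X), c(Y), spec$nucleus_semi_axes, beta_deg)
  phi <- k * spec$nucleus_delta_n * chord_n
  if (!is.null(spec$nucleolus_semi_axes)) {
    ctr <- rotate_x(spec$nucleolus_center_offset, beta_deg)
    chord_s <- ellipsoid_chord(c(X), c(Y), spec$nucleolus_semi_axes, beta_deg,
                               centre = ctr)
    phi <- phi + k * spec$nucleolus_delta_n * chord_s
  }
  matrix(phi, ny, nx)
}

#' Render a phantom frame set
#'
#' For every scheduled rolling angle, renders the analytic phase projection of
#' the rotated two-ellipsoid refractive-index model,
#' \deqn{\varphi(x,y) = \frac{2\pi}{\lambda}\left[\Delta n_{nuc}\,
#' \mathrm{chord}_{nuc}(x,y) + \Delta n_{nucleolus}\,
#' \mathrm{chord}_{nucleolus}(x,y)\right],}
#' where chord is the closed-form z-extent of the rotated ellipsoid at (x, y).
#' Gaussian phase noise of the specified sigma is added under the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_frames`: list with `phase_maps` (list
#'   of [phase_map()]), `truth` (tibble: frame, angle_deg), ground-truth
#'   volumes, and the spec.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  # support must stay strictly inside the frame at every angle: the projected
  # footprint is bounded by the bounding circle of radius max semi-axis
  half_fov <- min((spec$grid_shape - 1) / 2 * spec$pixel_size)
  if (max(spec$nucleus_semi_axes) >= half_fov - spec$pixel_size)
    abort("phantom clipped: projection support reaches the frame border")
  set.seed(spec$seed)
  maps <- lapply(spec$angle_schedule, function(beta) {
    phi <- render_phantom_frame(spec, beta)
    if (spec$noise_sigma_phase > 0)
      phi <- phi + matrix(stats::rnorm(length(phi), 0, spec$noise_sigma_phase),
                          nrow(phi), ncol(phi))
    phase_map(phi, spec$pixel_size, spec$wavelength)
  })
  v_nuc <- 4 / 3 * pi * prod(spec$nucleus_semi_axes)
  v_nol <- if (is.null(spec$nucleolus_semi_axes)) 0 else
    4 / 3 * pi * prod(spec$nucleolus_semi_axes)
  structure(
    list(phase_maps = maps,
         truth = tibble(frame = seq_along(spec$angle_schedule),
                        angle_deg = spec$angle_schedule),
         truth_volume_nucleus = v_nuc,
         truth_volume_nucleolus = v_nol,
         spec = spec),
    class = "phantom_frames"
  )
}

#' Ground-truth refractive-index volume of a phantom
#'
#' Voxelizes the two-ellipsoid model at a given rolling angle on an isotropic
#' grid `[y, z, x]` matching [tomogram()] layout. Used as the reference for
#' reconstruction-fidelity checks.
#'
#' @param spec A [phantom_spec()].
#' @param beta_deg Rolling angle of the voxelized orientation (degrees).
#' @param n_side Number of voxels along y and z (defaults to grid ny).
#' @return A [tomogram()] holding the true RI.
#' @export
phantom_truth_volume <- function(spec, beta_deg = 0, n_side = NULL) {
  ny <- if (is.null(n_side)) spec$grid_shape[1] else n_side
  nx <- spec$grid_shape[2]
  vx <- spec$pixel_size
  ys <- axis_coords(ny, vx); zs <- axis_coords(ny, vx); xs <- axis_coords(nx, vx)
  ri <- array(spec$background_ri, dim = c(ny, ny, nx))
  Mn <- ellipsoid_quadric(spec$nucleus_semi_axes, beta_deg)
  has_nol <- !is.null(spec$nucleolus_semi_axes)
  if (has_nol) {
    Ms <- ellipsoid_quadric(spec$nucleolus_semi_axes, beta_deg)
    ctr <- rotate_x(spec$nucleolus_center_offset, beta_deg)
  }
  Y <- matrix(ys, ny, ny); Z <- matrix(zs, ny, ny, byrow = TRUE)
  for (ix in seq_len(nx)) {
    x <- xs[ix]
    qn <- Mn[1, 1] * x^2 + 2 * Mn[1, 2] * x * Y + 2 * Mn[1, 3] * x * Z +
      Mn[2, 2] * Y^2 + 2 * Mn[2, 3] * Y * Z + Mn[3, 3] * Z^2
    sl <- matrix(spec$background_ri, ny, ny)
    sl[qn <= 1] <- spec$background_ri + spec$nucleus_delta_n
    if (has_nol) {
      xr <- x - ctr[1]; Yr <- Y - ctr[2]; Zr <- Z - ctr[3]
      qs <- Ms[1, 1] * xr^2 + 2 * Ms[1, 2] * xr * Yr + 2 * Ms[1, 3] * xr * Zr +
        Ms[2, 2] * Yr^2 + 2 * Ms[2, 3] * Yr * Zr + Ms[3, 3] * Zr^2
      sl[qs <= 1] <- sl[qs <= 1] + spec$nucleolus_delta_n
    }
    ri[, , ix] <- sl
  }
  tomogram(ri, vx, spec$background_ri)
}

#' Voxel-summation phase projection (cross-check renderer)
#'
#' Renders the same projection as [make_phantom()] by voxelizing the rotated
#' model and summing along z, rather than by the closed-form chord. Kept as an
#' independent numerical cross-check of the analytic renderer.
#'
#' @inheritParams phantom_truth_volume
#' @param z_step Integration step along z (um; default pixel_size / 2).
#' @return Numeric matrix of phase values (radians).
#' @export
render_phantom_frame_voxel <- function(spec, beta_deg, z_step = NULL) {
  if (is.null(z_step)) z_step <- spec$pixel_size / 2
  ny <- spec$grid_shape[1]; nx <- spec$grid_shape[2]
  xs <- axis_coords(nx, spec$pixel_size)
  ys <- axis_coords(ny, spec$pixel_size)
  zmax <- max(spec$nucleus_semi_axes) + z_step
  zs <- seq(-zmax, zmax, by = z_step)
  Mn <- ellipsoid_quadric(spec$nucleus_semi_axes, beta_deg)
  has_nol <- !is.null(spec$nucleolus_semi_axes)
  if (has_nol) {
    Ms <- ellipsoid_quadric(spec$nucleolus_semi_axes, beta_deg)
    ctr <- rotate_x(spec$nucleolus_center_offset, beta_deg)
  }
  k <- 2 * pi / spec$wavelength
  X <- matrix(xs, ny, nx, byrow = TRUE); Y <- matrix(ys, ny, nx)
  acc <- matrix(0, ny, nx)
  for (z in zs) {
    qn <- Mn[1, 1] * X^2 + 2 * Mn[1, 2] * X * Y + 2 * Mn[1, 3] * X * z +
      Mn[2, 2] * Y^2 + 2 * Mn[2, 3] * Y * z + Mn[3, 3] * z^2
    dn <- ifelse(qn <= 1, spec$nucleus_delta_n, 0)
    if (has_nol) {
      Xr <- X - ctr[1]; Yr <- Y - ctr[2]; zr <- z - ctr[3]
      qs <- Ms[1, 1] * Xr^2 + 2 * Ms[1, 2] * Xr * Yr + 2 * Ms[1, 3] * Xr * zr +
        Ms[2, 2] * Yr^2 + 2 * Ms[2, 3] * Yr * zr + Ms[3, 3] * zr^2
      dn <- dn + ifelse(qs <= 1, spec$nucleolus_delta_n, 0)
    }
    acc <- acc + dn
  }
  k * acc * z_step
}

#' Synthesize an off-axis hologram from a phase map
#'
#' Builds \eqn{H = |R + O|^2} with object beam \eqn{O = A_O e^{i\varphi}} and
#' a tilted plane-wave reference \eqn{R = A_R e^{2\pi i (f_x x + f_y y)}}
#' (carrier in cycles/pixel).
#'
#' @param qpm A [phase_map()].
#' @param carrier_freq Length-2 numeric c(fx, fy), cycles/pixel; each must be
#'   below Nyquist (|f| < 0.5).
#' @param ref_amp,obj_amp Positive beam amplitudes.
#' @return A [hologram()] (with `carrier_hint` set to the true carrier).
#' @export
synthesize_hologram <- function(qpm, carrier_freq = c(0.25, 0),
                                ref_amp = 1, obj_amp = 1) {
  stopifnot(inherits(qpm, "phase_map"))
  if (any(abs(carrier_freq) >= 0.5))
    abort("carrier frequency at or above Nyquist (|f| must be < 0.5 cycles/pixel)")
  if (ref_amp <= 0 || obj_amp <= 0) abort("beam amplitudes must be > 0")
  ny <- nrow(qpm$phase); nx <- ncol(qpm$phase)
  px <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  py <- matrix(0:(ny - 1), ny, nx)
  R <- ref_amp * exp(2i * pi * (carrier_freq[1] * px + carrier_freq[2] * py))
  O <- obj_amp * exp(1i * qpm$phase)
  H <- Mod(R + O)^2
  hologram(H, qpm$pixel_size, qpm$wavelength, carrier_hint = carrier_freq)
}
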