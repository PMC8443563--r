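#' Tamura contrast coefficient
#'
#' Sharpness/contrast metric \eqn{\sqrt{\sigma/\mu}} of a non-negative image,
#' with sigma the population standard deviation and mu the mean. Maximised at
#' best focus; used by [autofocus()].
#'
#' @param image Numeric matrix (or vector) with positive mean.
#' @return Scalar Tamura coefficient.
#' @export
tamura <- function(image) {
  mu <- mean(image)
  if (!is.finite(mu) || mu <= 0) abort("tamura requires a positive image mean")
  sqrt(sd_pop(c(image)) / mu)
}

# raised-cosine circular window centred at (r0, c0) bins (1-based), radius in
# bins, edge fraction of radius over which the taper falls from 1 to 0
spectral_window <- function(ny, nx, r0, c0, radius, edge = 0.3) {
  # distances on the periodic frequency grid
  dr <- abs(outer(seq_len(ny) - r0, rep(0, nx), "+"))
  dr <- pmin(dr, ny - dr)
  dc <- abs(outer(rep(0, ny), seq_len(nx) - c0, "+"))
  dc <- pmin(dc, nx - dc)
  d <- sqrt(dr^2 + dc^2)
  r_in <- radius * (1 - edge)
  w <- matrix(0, ny, nx)
  w[d <= r_in] <- 1
  tap <- d > r_in & d < radius
  w[tap] <- 0.5 * (1 + cos(pi * (d[tap] - r_in) / (radius - r_in)))
  w
}

#' Demodulate an off-axis hologram
#'
#' Isolates the +1-order sideband \eqn{R^*O} of \eqn{H = |R|^2 + |O|^2 + R^*O
#' + RO^*} by spectral windowing around the carrier peak, re-centres it
#' (removing the carrier), and zeroes the background phase via the median over
#' a border ring.
#'
#' @param holo A [hologram()]. If `carrier_hint` is set, the sideband is
#'   searched near the hinted frequency; otherwise the strongest off-centre
#'   spectral peak is used.
#' @param window_radius_frac Window radius as a fraction of the carrier
#'   magnitude (default 0.5).
#' @param background_ring Width (pixels) of the border ring whose median phase
#'   is subtracted (default 8; 0 disables).
#' @return A [complex_field()] at the acquisition plane.
#' @export
demodulate_offaxis <- function(holo, window_radius_frac = 0.5,
                               background_ring = 8) {
  stopifnot(inherits(holo, "hologram"))
  H <- holo$intensity
  ny <- nrow(H); nx <- ncol(H)
  FH <- fft(H)
  mag <- Mod(FH)
  # periodic distance of every bin from DC (bin 1,1)
  fr <- fft_freq(ny); fc <- fft_freq(nx)
  dist_dc <- sqrt(outer(fr^2, rep(1, nx)) + outer(rep(1, ny), fc^2))
  dc_mask <- dist_dc < 0.03  # DC skirt exclusion (cycles/pixel)
  cand <- mag
  cand[dc_mask] <- 0
  global_peak <- max(cand)
  if (!is.null(holo$carrier_hint)) {
    # hint is the reference-beam tilt (fx, fy); the object order R*O sits at
    # the mirrored frequency -(fx, fy)
    f <- -holo$carrier_hint
    dh_r <- (fr - f[2]); dh_r <- pmin(abs(dh_r), 1 - abs(dh_r))
    dh_c <- (fc - f[1]); dh_c <- pmin(abs(dh_c), 1 - abs(dh_c))
    dist_hint <- sqrt(outer(dh_r^2, rep(1, nx)) + outer(rep(1, ny), dh_c^2))
    carrier_mag <- sqrt(sum(f^2))
    local <- cand
    local[dist_hint > window_radius_frac * max(carrier_mag, 0.05)] <- 0
    if (max(local) < 0.5 * global_peak)
      abort("no carrier found near carrier_hint")
    idx <- which(local == max(local), arr.ind = TRUE)[1, ]
  } else {
    if (global_peak < 1e-6 * mag[1, 1] || global_peak == 0)
      abort("no carrier found: spectrum has no off-centre peak above the DC skirt")
    idx <- which(cand == global_peak, arr.ind = TRUE)[1, ]
  }
  peak_freq <- c(fc[idx[2]], fr[idx[1]])           # (fx, fy) cycles/pixel
  radius_bins <- window_radius_frac * sqrt((peak_freq[1] * nx)^2 +
                                             (peak_freq[2] * ny)^2)
  w <- spectral_window(ny, nx, idx[1], idx[2], radius_bins)
  Fs <- FH * w
  # circular shift so the carrier bin lands on DC
  Fs <- Fs[((seq_len(ny) - 1 + (idx[1] - 1)) %% ny) + 1,
           ((seq_len(nx) - 1 + (idx[2] - 1)) %% nx) + 1, drop = FALSE]
  field <- fft(Fs, inverse = TRUE) / (ny * nx)
  # remove the sub-bin carrier residual: the median wrapped phase gradient
  # estimates the leftover linear ramp robustly against the object
  ph <- Arg(field)
  wrapg <- function(g) atan2(sin(g), cos(g))
  ramp_x <- median(wrapg(ph[, 2:nx] - ph[, 1:(nx - 1)]))
  ramp_y <- median(wrapg(ph[2:ny, ] - ph[1:(ny - 1), ]))
  if (abs(ramp_x) > 1e-9 || abs(ramp_y) > 1e-9) {
    px <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
    py <- matrix(0:(ny - 1), ny, nx)
    field <- field * exp(-1i * (ramp_x * px + ramp_y * py))
  }
  if (background_ring > 0) {
    ring <- matrix(FALSE, ny, nx)
    b <- background_ring
    ring[c(seq_len(b), ny - seq_len(b) + 1), ] <- TRUE
    ring[, c(seq_len(b), nx - seq_len(b) + 1)] <- TRUE
    bg <- median(Arg(field[ring]))
    field <- field * exp(-1i * bg)
  }
  complex_field(field, holo$pixel_size, holo$wavelength)
}

#' Angular-spectrum propagation
#'
#' Propagates a complex field by `dz` along the optical axis with the
#' angular-spectrum kernel \eqn{\exp(i 2\pi dz \sqrt{1/\lambda^2 - f_x^2 -
#' f_y^2})}; evanescent components are zeroed. Unitary on the propagating
#' band, so energy is conserved.
#'
#' @param field A [complex_field()].
#' @param dz Propagation distance (um), positive or negative.
#' @return A [complex_field()] with updated `z_offset`.
#' @export
propagate <- function(field, dz) {
  stopifnot(inherits(field, "complex_field"), is.finite(dz))
  if (dz == 0) return(field)
  U <- field$values
  ny <- nrow(U); nx <- ncol(U)
  fx <- fft_freq(nx) / field$pixel_size
  fy <- fft_freq(ny) / field$pixel_size
  f2 <- outer(fy^2, rep(1, nx)) + outer(rep(1, ny), fx^2)
  arg <- 1 / field$wavelength^2 - f2
  kz <- matrix(0, ny, nx)
  prop_band <- arg > 0
  kz[prop_band] <- 2 * pi * sqrt(arg[prop_band])
  kern <- matrix(0 + 0i, ny, nx)
  kern[prop_band] <- exp(1i * kz[prop_band] * dz)
  out <- fft(fft(U) * kern, inverse = TRUE) / (ny * nx)
  complex_field(out, field$pixel_size, field$wavelength,
                z_offset = field$z_offset + dz)
}

# focus metric representations; both are gradient magnitudes so the Tamura
# input is non-negative and insensitive to the arbitrary phase offset / wrap
focus_metric <- function(field, metric_on, region = NULL) {
  grad_mag <- function(img, wrap = FALSE) {
    gx <- img[, c(2:ncol(img), ncol(img))] - img
    gy <- img[c(2:nrow(img), nrow(img)), ] - img
    if (wrap) {
      gx <- atan2(sin(gx), cos(gx))
      gy <- atan2(sin(gy), cos(gy))
    }
    sqrt(gx^2 + gy^2)
  }
  g <- if (metric_on == "amplitude_gradient") {
    grad_mag(Mod(field$values))
  } else {
    grad_mag(Arg(field$values), wrap = TRUE)
  }
  ny <- nrow(g); nx <- ncol(g)
  if (is.null(region)) {
    # central region: periodic propagation wraps energy in from the borders
    # at large defocus and would fake contrast there
    my <- max(1, round(ny / 8)); mx <- max(1, round(nx / 8))
    g <- g[my:(ny - my + 1), mx:(nx - mx + 1)]
  } else {
    g <- g[region$rows, region$cols, drop = FALSE]
  }
  if (mean(g) <= 0) return(0)
  tamura(g)
}

#' Tamura-coefficient autofocus
#'
#' Coarse grid search over a refocus range followed by golden-section
#' refinement of the Tamura coefficient of the chosen representation
#' (amplitude-gradient magnitude for amplitude objects, phase for quantitative
#' phase maps). Ties are broken toward the smallest |z|. If the coarse metric
#' curve is not unimodal a warning is issued and the global grid maximum is
#' returned unrefined.
#'
#' @param field A [complex_field()].
#' @param z_range Length-2 numeric c(z_min, z_max) in um.
#' @param n_steps Number of coarse grid points (>= 3).
#' @param metric_on `"phase"` (default) or `"amplitude_gradient"`.
#' @param roi Optional logical matrix: the metric is evaluated over the
#'   bounding box of `roi` (with a small margin) instead of the central
#'   region, so a single object can drive the focus.
#' @return Best-focus offset z_F (um), with the coarse metric curve attached
#'   as attribute `"metric"`.
#' @export
autofocus <- function(field, z_range, n_steps = 21,
                      metric_on = c("phase", "amplitude_gradient"),
                      roi = NULL) {
  metric_on <- match.arg(metric_on)
  stopifnot(length(z_range) == 2, z_range[1] < z_range[2], n_steps >= 3)
  region <- NULL
  if (!is.null(roi)) {
    idx <- which(roi > 0, arr.ind = TRUE)
    if (nrow(idx) == 0) abort("roi is empty")
    m <- 4
    region <- list(
      rows = max(1, min(idx[, 1]) - m):min(nrow(field$values), max(idx[, 1]) + m),
      cols = max(1, min(idx[, 2]) - m):min(ncol(field$values), max(idx[, 2]) + m))
  }
  zs <- seq(z_range[1], z_range[2], length.out = n_steps)
  vals <- vapply(zs, function(z)
    focus_metric(propagate(field, z), metric_on, region), numeric(1))
  curve <- tibble(z = zs, metric = vals)
  # count significant local maxima (prominent above mid-range)
  rng <- max(vals) - min(vals)
  thr <- min(vals) + 0.5 * rng
  is_peak <- vapply(seq_len(n_steps), function(i) {
    left <- if (i > 1) vals[i - 1] else -Inf
    right <- if (i < n_steps) vals[i + 1] else -Inf
    vals[i] > left && vals[i] >= right && vals[i] > thr
  }, logical(1))
  n_peaks <- sum(is_peak)
  flat <- rng < 1e-6 * max(abs(vals), 1e-12)
  best <- which(vals == max(vals))
  best <- best[which.min(abs(zs[best]))]  # ties toward smallest |z|
  if (flat || n_peaks != 1) {
    warn("autofocus metric is not unimodal over the range; returning global grid maximum")
    z_f <- zs[best]
  } else {
    lo <- zs[max(1, best - 1)]; hi <- zs[min(n_steps, best + 1)]
    opt <- optimize(function(z)
      focus_metric(propagate(field, z), metric_on, region),
      lower = lo, upper = hi, maximum = TRUE, tol = (hi - lo) * 1e-3)
    z_f <- opt$maximum
  }
  attr(z_f, "metric") <- curve
  z_f
}

#' Phase of a complex field, unwrapped if needed
#'
#' Extracts \eqn{\psi_O = \arg\{C\}} and applies 2D least-squares phase
#' unwrapping when the wrapped-gradient check fails (any |grad phi| > pi/2
#' per pixel), since nuclei can accumulate multi-radian phase.
#'
#' @param field A [complex_field()].
#' @param unwrap `"auto"` (default), `TRUE`, or `FALSE`.
#' @return A [phase_map()].
#' @export
field_phase <- function(field, unwrap = "auto") {
  ph <- Arg(field$values)
  need <- if (identical(unwrap, "auto")) {
    gx <- diff(t(ph)); gy <- diff(ph)
    wrapped <- function(g) atan2(sin(g), cos(g))
    max(abs(wrapped(gx)), abs(wrapped(gy))) > pi / 2 &&
      (max(ph) - min(ph)) > 1.9 * pi
  } else isTRUE(unwrap)
  if (need) ph <- unwrap_phase(ph)
  phase_map(ph, field$pixel_size, field$wavelength)
}

# ---- DCT-based least-squares 2D phase unwrapping -------------------------

# DCT-II matrix: M[k, n] = cos(pi * (n + 1/2) * k / N), k, n = 0..N-1
dct_mat <- function(N) {
  k <- 0:(N - 1); n <- 0:(N - 1)
  outer(k, n, function(k, n) cos(pi * (n + 0.5) * k / N))
}

dct2d <- function(x, Mr, Mc) Mr %*% x %*% t(Mc)

idct2d <- function(X, Mr, Mc) {
  n <- nrow(X); m <- ncol(X)
  wr <- c(1 / n, rep(2 / n, n - 1))
  wc <- c(1 / m, rep(2 / m, m - 1))
  t(Mr) %*% (X * outer(wr, wc)) %*% Mc
}

#' Least-squares 2D phase unwrapping
#'
#' Unweighted Ghiglia-Romero unwrapping: solves the discrete Poisson equation
#' driven by the wrapped phase gradients via DCT (Neumann boundaries), then
#' makes the result congruent to the input modulo 2*pi.
#'
#' @param psi Wrapped phase matrix (radians, values in (-pi, pi]).
#' @return Unwrapped phase matrix.
#' @export
unwrap_phase <- function(psi) {
  wrap <- function(g) atan2(sin(g), cos(g))
  n <- nrow(psi); m <- ncol(psi)
  dx <- matrix(0, n, m); dy <- matrix(0, n, m)
  dx[, 1:(m - 1)] <- wrap(psi[, 2:m] - psi[, 1:(m - 1)])
  dy[1:(n - 1), ] <- wrap(psi[2:n, ] - psi[1:(n - 1), ])
  rho <- (dx - cbind(0, dx[, 1:(m - 1)])) + (dy - rbind(0, dy[1:(n - 1), ]))
  Mr <- dct_mat(n); Mc <- dct_mat(m)
  D <- dct2d(rho, Mr, Mc)
  denom <- outer(2 * cos(pi * (0:(n - 1)) / n) - 2,
                 2 * cos(pi * (0:(m - 1)) / m) - 2, "+")
  denom[1, 1] <- 1
  PHI <- D / denom
  PHI[1, 1] <- 0
  phi <- idct2d(PHI, Mr, Mc)
  # congruence: snap to the measured phase modulo 2*pi
  psi + 2 * pi * round((phi - psi) / (2 * pi))
}
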