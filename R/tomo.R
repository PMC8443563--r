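#' Filtered back-projection of aligned phase projections
#'
#' Reconstructs the 3D refractive-index distribution of a nucleus from its
#' centred, axis-aligned phase projections and the recovered rolling angles.
#' Each slice perpendicular to the rotation axis x is reconstructed
#' independently: the 1D phase profiles phi(y; theta_k) are ramp-filtered
#' (Ram-Lak, optionally Hann-apodized) and back-projected at the given
#' non-uniform angles with trapezoidal local-spacing weights normalised to
#' pi. The reconstructed line-integral density (radians per um) is converted
#' to refractive index by \eqn{n = n_{bg} + g\,\lambda/(2\pi)} under the
#' straight-ray projection assumption.
#'
#' Angles beyond 180 degrees are folded into [0, 180) using the parallel-ray
#' identity p(t; theta + 180) = p(-t; theta). Sequences spanning less than
#' 180 degrees are reconstructed with a warning (limited-angle degradation);
#' less than 90 degrees is an error.
#'
#' @param projections List of [phase_map()]s (all same shape/pixel size),
#'   aligned so the rotation axis is x and the centroid is at frame centre.
#' @param angles_deg Numeric rolling angle per projection (degrees), or an
#'   `angle_series` from [unwrap_angles()] (its valid frames are used).
#' @param background_ri Background refractive index (default 1.368).
#' @param wavelength Um; default taken from the first projection.
#' @param filter `"ramlak"` (default) or `"hann"`.
#' @param clip_below Negative-ringing clip: values below
#'   `background_ri - clip_below` are clipped to the background (default
#'   0.02); the raw volume is retained in the `ri_raw` field.
#' @param pad_factor Zero-padding factor of the ramp filtering (default 4;
#'   larger padding suppresses circular-convolution leakage of the slowly
#'   decaying filter tails and improves mass conservation).
#' @return A [tomogram()] (`ri` indexed `[y, z, x]`).
#' @export
fbp_reconstruct <- function(projections, angles_deg, background_ri = 1.368,
                            wavelength = NULL, filter = c("ramlak", "hann"),
                            clip_below = 0.02, pad_factor = 4) {
  filter <- match.arg(filter)
  if (inherits(angles_deg, "angle_series")) {
    keep <- angles_deg$valid
    projections <- projections[keep]
    angles_deg <- angles_deg$theta_deg[keep]
  }
  stopifnot(length(projections) == length(angles_deg))
  if (length(projections) < 8) abort("need at least 8 valid projections")
  px <- projections[[1]]$pixel_size
  if (is.null(wavelength)) wavelength <- projections[[1]]$wavelength
  dims <- vapply(projections, function(p) dim(p$phase), integer(2))
  if (any(dims != dims[, 1])) abort("all projections must share the same shape")
  span <- max(angles_deg) - min(angles_deg)
  if (span < 90) abort("angular span < 90 degrees: too little rotation for reconstruction")
  mean_gap <- span / max(1, length(angles_deg) - 1)
  if (span + mean_gap < 180) warn("angular span < 180 degrees: limited-angle reconstruction")
  if (is.unsorted(angles_deg)) {
    warn("angles not monotone; sorting projections by angle")
    o <- order(angles_deg)
    projections <- projections[o]
    angles_deg <- angles_deg[o]
  }
  ny <- dims[1, 1]; nx <- dims[2, 1]
  # fold to [0, 180): theta + 180 views the mirrored profile
  th <- angles_deg %% 360
  flip <- th >= 180
  th <- th %% 180
  o <- order(th)
  th <- th[o]; flip <- flip[o]; projections <- projections[o]
  # drop near-duplicate angles (within 0.01 deg) to keep weights sane
  keep <- c(TRUE, diff(th) > 0.01)
  th <- th[keep]; flip <- flip[keep]; projections <- projections[keep]
  K <- length(th)
  th_rad <- th * pi / 180
  # trapezoidal local-spacing weights, periodic over the folded half-turn
  gaps <- diff(c(th_rad, th_rad[1] + pi))          # K gaps, wraps around
  w <- (gaps + c(gaps[K], gaps[-K])) / 2
  w <- w * pi / sum(w)
  # ramp filter on zero-padded profiles
  nfft <- 2^ceiling(log2(pad_factor * ny))
  nu <- fft_freq(nfft) / px                         # cycles per um
  ramp <- abs(nu)
  if (filter == "hann") {
    nu_max <- max(abs(nu))
    ramp <- ramp * 0.5 * (1 + cos(pi * nu / nu_max))
  }
  ys <- axis_coords(ny, px)
  # filtered profiles: for each projection, a ny x nx matrix
  filtered <- lapply(seq_len(K), function(k) {
    P <- projections[[k]]$phase
    if (flip[k]) P <- P[ny:1, , drop = FALSE]
    Ppad <- rbind(P, matrix(0, nfft - ny, nx))
    Q <- mvfft(Ppad) * ramp
    Re(mvfft(Q, inverse = TRUE))[1:ny, , drop = FALSE] / nfft
  })
  # precompute back-projection interpolation (same for every slice)
  Y <- matrix(ys, ny, ny)                    # rows y, cols z
  Z <- matrix(ys, ny, ny, byrow = TRUE)
  interp_idx <- lapply(seq_len(K), function(k) {
    t <- Y * cos(th_rad[k]) - Z * sin(th_rad[k])
    pos <- (t - ys[1]) / px + 1
    i0 <- floor(pos)
    fr <- pos - i0
    ok <- i0 >= 1 & i0 <= ny - 1
    list(i0 = ifelse(ok, i0, 1L), fr = ifelse(ok, fr, 0), ok = ok)
  })
  vol <- array(0, dim = c(ny, ny, nx))
  for (ix in seq_len(nx)) {
    acc <- matrix(0, ny, ny)
    for (k in seq_len(K)) {
      q <- filtered[[k]][, ix]
      ii <- interp_idx[[k]]
      val <- (q[ii$i0] * (1 - ii$fr) + q[ii$i0 + 1] * ii$fr) * ii$ok
      acc <- acc + w[k] * matrix(val, ny, ny)
    }
    vol[, , ix] <- acc
  }
  ri_raw <- background_ri + vol * wavelength / (2 * pi)
  ri <- ri_raw
  ri[ri < background_ri - clip_below] <- background_ri
  tomogram(ri, px, background_ri, ri_raw = ri_raw)
}

#' Extract an orthogonal slice from a tomogram
#'
#' @param tomo A [tomogram()] (`ri` indexed `[y, z, x]`).
#' @param axis `"x"`, `"y"` or `"z"` -- the axis perpendicular to the slice.
#' @param index 1-based index along that axis; default the central slice.
#' @return Numeric matrix of RI values with attributes `coords` (row/col
#'   physical coordinates, um) and `axis`.
#' @export
slice_tomogram <- function(tomo, axis = c("x", "y", "z"), index = NULL) {
  axis <- match.arg(axis)
  d <- dim(tomo$ri)
  nmax <- switch(axis, y = d[1], z = d[2], x = d[3])
  if (is.null(index)) index <- (nmax + 1) %/% 2
  if (index < 1 || index > nmax) abort("slice index out of range")
  sl <- switch(axis,
               x = tomo$ri[, , index],
               y = tomo$ri[index, , ],
               z = tomo$ri[, index, ])
  rows <- switch(axis, x = d[1], y = d[2], z = d[1])
  cols <- switch(axis, x = d[2], y = d[3], z = d[3])
  attr(sl, "coords") <- list(row = axis_coords(rows, tomo$voxel_size),
                             col = axis_coords(cols, tomo$voxel_size))
  attr(sl, "axis") <- axis
  sl
}

#' Re-project a tomogram at given rolling angles
#'
#' Forward projection (straight-ray line integral along z after rotating the
#' volume about x) of the reconstructed refractive-index contrast back into
#' phase maps; used to check projection consistency of a reconstruction.
#'
#' @param tomo A [tomogram()].
#' @param angles_deg Angles at which to project (degrees).
#' @param wavelength Um.
#' @return List of phase matrices (radians), one per angle.
#' @export
reproject_tomogram <- function(tomo, angles_deg, wavelength) {
  d <- dim(tomo$ri)
  ny <- d[1]; nx <- d[3]
  vx <- tomo$voxel_size
  ys <- axis_coords(ny, vx)
  k <- 2 * pi / wavelength
  dn <- tomo$ri - tomo$background_ri
  Y <- matrix(ys, ny, ny); Z <- matrix(ys, ny, ny, byrow = TRUE)
  lapply(angles_deg, function(a) {
    t <- a * pi / 180
    # sample the reference volume along the rotated rays
    src_y <- Y * cos(t) + Z * sin(t)
    src_z <- -Y * sin(t) + Z * cos(t)
    r <- (src_y - ys[1]) / vx
    c <- (src_z - ys[1]) / vx
    out <- matrix(0, ny, nx)
    for (ix in seq_len(nx)) {
      out[, ix] <- rowSums(matrix(bilinear_sample(dn[, , ix], r, c), ny, ny)) *
        vx * k
    }
    out
  })
}
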