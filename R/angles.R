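#' Segment a nucleus as an elliptic binary mask
#'
#' Thresholds the phase ROI, keeps the largest connected component, and fits
#' the equivalent ellipse from its central second moments (full axis lengths
#' `4 * sqrt(eigenvalue)`, exact for a filled ellipse). The returned mask is
#' the filled fitted ellipse, as used to segment the rotating nucleus frame
#' by frame.
#'
#' @param qpm A [phase_map()] (region of interest containing one nucleus).
#' @param threshold Phase threshold (radians). Default: background median
#'   plus `threshold_frac` of the (max - median) excursion.
#' @param threshold_frac Fraction used by the default threshold (0.1).
#' @param min_area Minimum component area in pixels (default 16).
#' @return List with `ellipse` (one-row tibble: cx, cy, major_len,
#'   minor_len, tilt_deg, circular flag -- lengths in um, centre in um) and
#'   `mask` (logical matrix, the filled ellipse).
#' @export
segment_ellipse <- function(qpm, threshold = NULL, threshold_frac = 0.1,
                            min_area = 16) {
  stopifnot(inherits(qpm, "phase_map"))
  ph <- qpm$phase
  if (is.null(threshold)) {
    bg <- median(ph)
    threshold <- bg + threshold_frac * (max(ph) - bg)
  }
  bw <- ph > threshold
  if (sum(bw) < min_area) abort("nucleus not found: no component above minimum area")
  lab <- EBImage::bwlabel(bw * 1)
  tab <- tabulate(lab[lab > 0])
  big <- which.max(tab)
  if (tab[big] < min_area) abort("nucleus not found: no component above minimum area")
  comp <- lab == big
  idx <- which(comp, arr.ind = TRUE)
  cx <- mean(idx[, 2] - 1); cy <- mean(idx[, 1] - 1)
  x <- idx[, 2] - 1 - cx; y <- idx[, 1] - 1 - cy
  C <- matrix(c(mean(x^2), mean(x * y), mean(x * y), mean(y^2)), 2, 2)
  eg <- eigen(C, symmetric = TRUE)
  major_px <- 4 * sqrt(eg$values[1])
  minor_px <- 4 * sqrt(max(eg$values[2], 0))
  v <- eg$vectors[, 1]
  tilt <- atan2(v[2], v[1]) * 180 / pi
  if (tilt <= -90) tilt <- tilt + 180
  if (tilt > 90) tilt <- tilt - 180
  px <- qpm$pixel_size
  ell <- tibble(cx = cx * px, cy = cy * px,
                major_len = major_px * px, minor_len = minor_px * px,
                tilt_deg = tilt,
                circular = minor_px / major_px > 0.95)
  # filled fitted ellipse as the segmentation mask
  nx <- ncol(ph); ny <- nrow(ph)
  X <- matrix(0:(nx - 1), ny, nx, byrow = TRUE) - cx
  Y <- matrix(0:(ny - 1), ny, nx) - cy
  th <- tilt * pi / 180
  u <- X * cos(th) + Y * sin(th)
  w <- -X * sin(th) + Y * cos(th)
  mask <- (u / (major_px / 2))^2 + (w / (minor_px / 2))^2 <= 1
  list(ellipse = ell, mask = mask)
}

#' Centre and align a segmented nucleus projection
#'
#' Translates the nucleus centroid to the frame centre and rotates the image
#' plane by minus the ellipse tilt (bilinear interpolation), so the major
#' axis -- the rotation axis -- lies along x. Pixels outside a slightly
#' dilated ellipse support are zeroed so the aligned map contains only the
#' segmented nucleus.
#'
#' @param qpm A [phase_map()].
#' @param ellipse One-row ellipse tibble from [segment_ellipse()].
#' @param mask_pad Relative padding of the masking ellipse (default 0.08).
#' @param mask_background If `TRUE` (default) zero outside the padded ellipse.
#' @return A [phase_map()] of the same shape, aligned and centred.
#' @export
align_and_center <- function(qpm, ellipse, mask_pad = 0.08,
                             mask_background = TRUE) {
  stopifnot(inherits(qpm, "phase_map"))
  ph <- qpm$phase
  ny <- nrow(ph); nx <- ncol(ph)
  px <- qpm$pixel_size
  cx <- ellipse$cx / px; cy <- ellipse$cy / px
  th <- ellipse$tilt_deg * pi / 180
  ctr_x <- (nx - 1) / 2; ctr_y <- (ny - 1) / 2
  X <- matrix(0:(nx - 1), ny, nx, byrow = TRUE) - ctr_x
  Y <- matrix(0:(ny - 1), ny, nx) - ctr_y
  # inverse map: rotate output coords by +tilt, then shift to the centroid
  src_x <- cx + X * cos(th) - Y * sin(th)
  src_y <- cy + X * sin(th) + Y * cos(th)
  out <- matrix(bilinear_sample(ph, c(src_y), c(src_x)), ny, nx)
  if (mask_background) {
    a <- ellipse$major_len / 2 / px * (1 + mask_pad)
    b <- ellipse$minor_len / 2 / px * (1 + mask_pad)
    keep <- (X / a)^2 + (Y / b)^2 <= 1
    out[!keep] <- 0
  }
  phase_map(out, px, qpm$wavelength, qpm$frame_time)
}

#' Minor-axis-length curve of a rotating nucleus
#'
#' Collects the per-frame minor-axis lengths l_k of the elliptic segmentation
#' masks, locates the extrema of the (optionally smoothed) curve, and labels
#' each extreme `global_min` / `global_max` when its value is within a
#' tolerance of the series minimum / maximum, else `local`. Frames at local
#' extrema are the angularly indeterminate ones.
#'
#' @param ellipses List of one-row ellipse tibbles (from [segment_ellipse()])
#'   or a data frame with a `minor_len` column.
#' @param smooth_window Moving-average window for extrema detection only
#'   (odd; default 3; 1 disables).
#' @param global_tol Tolerance for the global label, as a fraction of the
#'   curve range (default 0.02).
#' @param min_prominence Noise rejection: adjacent extrema pairs whose
#'   values differ by less than this fraction of the curve range are treated
#'   as a spurious wiggle and cancelled (default 0.1).
#' @return An object of class `minor_axis_curve`: tibble (frame, minor_len,
#'   major_len, smoothed) with attributes `extrema` (tibble: frame, value,
#'   kind, side) and `smoothing_params`.
#' @export
build_minor_axis_curve <- function(ellipses, smooth_window = 3,
                                   global_tol = 0.02, min_prominence = 0.1) {
  df <- if (is.data.frame(ellipses)) as_tibble(ellipses)
        else dplyr::bind_rows(ellipses)
  n <- nrow(df)
  if (n < 5) abort("need at least 5 frames")
  l <- df$minor_len
  sm <- if (smooth_window > 1) {
    k <- smooth_window %/% 2
    pad <- c(rep(l[1], k), l, rep(l[n], k))
    as.numeric(stats::filter(pad, rep(1 / smooth_window, smooth_window),
                             sides = 2))[(k + 1):(k + n)]
  } else l
  d <- diff(sm)
  # interior sign changes of the first difference (plateau-safe)
  s <- sign(d)
  nz <- which(s != 0)
  ext_frames <- integer(0); ext_side <- character(0)
  if (length(nz) >= 2) {
    for (j in seq_len(length(nz) - 1)) {
      if (s[nz[j]] != s[nz[j + 1]]) {
        ext_frames <- c(ext_frames, nz[j] + 1)  # frame after the last move
        ext_side <- c(ext_side, if (s[nz[j]] > 0) "max" else "min")
      }
    }
  }
  rng <- max(l) - min(l)
  # persistence pruning: cancel adjacent extrema pairs of small amplitude
  # (noise wiggles), preserving min/max alternation
  if (length(ext_frames) >= 2 && min_prominence > 0) {
    repeat {
      if (length(ext_frames) < 2) break
      amp <- abs(diff(sm[ext_frames]))
      j <- which.min(amp)
      if (amp[j] >= min_prominence * rng) break
      ext_frames <- ext_frames[-c(j, j + 1)]
      ext_side <- ext_side[-c(j, j + 1)]
    }
  }
  kind <- vapply(seq_along(ext_frames), function(j) {
    v <- l[ext_frames[j]]
    if (ext_side[j] == "max" && max(l) - v <= global_tol * rng) "global_max"
    else if (ext_side[j] == "min" && v - min(l) <= global_tol * rng) "global_min"
    else "local"
  }, character(1))
  out <- tibble(frame = seq_len(n), minor_len = l,
                major_len = if ("major_len" %in% names(df)) df$major_len else NA_real_,
                smoothed = sm)
  attr(out, "extrema") <- tibble(frame = ext_frames, value = l[ext_frames],
                                 side = ext_side, kind = kind)
  attr(out, "smoothing_params") <- list(smooth_window = smooth_window,
                                        global_tol = global_tol,
                                        min_prominence = min_prominence)
  class(out) <- c("minor_axis_curve", class(out))
  out
}

#' Projected minor-axis length of a rotated triaxial ellipsoid
#'
#' For an ellipsoid with semi-axes (a, b, c), a along the in-plane rotation
#' axis x, rotated by the rolling angle beta about x, the projection on the
#' image plane is an ellipse with constant major axis 2a and minor axis
#' \deqn{l(\beta) = 2\sqrt{b^2\cos^2\beta + c^2\sin^2\beta}.}
#'
#' @param beta_deg Rolling angle(s), degrees.
#' @param b_semi,c_semi Minor semi-axes (um), `b_semi >= c_semi > 0`.
#' @return Minor-axis length(s) in um.
#' @export
ellipsoid_minor_axis <- function(beta_deg, b_semi, c_semi) {
  stopifnot(b_semi >= c_semi, c_semi > 0)
  b <- beta_deg * pi / 180
  2 * sqrt(b_semi^2 * cos(b)^2 + c_semi^2 * sin(b)^2)
}

#' Invert the minor-axis curve for the folded rolling angle
#'
#' Inverse of [ellipsoid_minor_axis()] on the principal interval:
#' \deqn{\beta = \arccos\sqrt{\frac{(l/2)^2 - c^2}{b^2 - c^2}}} in degrees,
#' monotone decreasing in l, with beta in [0, 90].
#'
#' @param l Minor-axis length(s), um.
#' @param b_semi,c_semi Lookup-ellipsoid minor semi-axes (um).
#' @param clip_tol Lengths outside `[2c, 2b]` by at most this amount (um) are
#'   clipped with a warning; beyond it is an error. Default 1 pixel at the
#'   instrument scale (0.17 um) unless overridden.
#' @return Folded angle(s) beta in degrees, `[0, 90]`.
#' @export
invert_angle <- function(l, b_semi, c_semi, clip_tol = 0.17) {
  if (b_semi <= c_semi) abort("rotation unobservable: circular cross-section (b = c)")
  lo <- 2 * c_semi; hi <- 2 * b_semi
  if (any(l < lo - clip_tol | l > hi + clip_tol))
    abort("minor-axis length outside the admissible [2c, 2b] interval")
  if (any(l < lo | l > hi))
    warn("minor-axis length slightly outside [2c, 2b]; clipped")
  l <- pmin(pmax(l, lo), hi)
  ratio <- ((l / 2)^2 - c_semi^2) / (b_semi^2 - c_semi^2)
  acos(sqrt(pmin(pmax(ratio, 0), 1))) * 180 / pi
}

#' Unwrap folded angles into monotone rolling angles
#'
#' The minor-axis curve folds the rolling angle into [0, 90] degrees; every
#' extreme of the curve marks the passage of a 90-degree cell boundary. This
#' reconstructs monotone non-decreasing rolling angles theta_k by reflecting
#' the folded angles segment by segment and adding 90 degrees per passed
#' extreme. Frames at local (non-global) extrema are indeterminate and marked
#' invalid. The lookup semi-axes default to half the maximum and minimum
#' observed minor-axis lengths, so theta at successive global extremes
#' differs by an exact multiple of 90 degrees.
#'
#' @param curve A [build_minor_axis_curve()] result.
#' @param b_semi,c_semi Lookup-ellipsoid semi-axes (um); default half the
#'   max/min observed minor-axis length.
#' @param clip_tol Passed to [invert_angle()].
#' @param enforce_monotone Apply a running-maximum repair of small
#'   noise-induced decreases (default TRUE).
#' @return An object of class `angle_series`: tibble (frame, minor_len,
#'   beta_deg, theta_deg, valid, segment) with attributes `extrema`
#'   (including the nominal theta at each extreme), `max_rolling_angle`,
#'   `b_semi`, `c_semi`.
#' @export
unwrap_angles <- function(curve, b_semi = NULL, c_semi = NULL,
                          clip_tol = NULL, enforce_monotone = TRUE) {
  stopifnot(inherits(curve, "minor_axis_curve"))
  ext <- attr(curve, "extrema")
  if (nrow(ext) == 0)
    abort("insufficient rotation (< 90 degrees): no extreme found in the minor-axis curve")
  l <- curve$minor_len
  n <- length(l)
  if (is.null(b_semi)) b_semi <- max(l) / 2
  if (is.null(c_semi)) c_semi <- min(l) / 2
  if (is.null(clip_tol)) clip_tol <- 0.02 * (b_semi - c_semi) + 1e-9
  beta <- invert_angle(l, b_semi, c_semi, clip_tol = clip_tol)
  # segment index = number of extrema strictly before each frame (an extreme
  # frame closes its own segment; at a global extreme beta is exactly 0 or 90
  # so both adjacent formulas agree there)
  seg <- findInterval(seq_len(n) - 0.5, ext$frame)
  # direction of each segment: beta ascends toward a min of l, descends after
  # it; equivalently a segment that ends at a "min" extreme is ascending and
  # a segment that starts at a "min" is descending
  n_seg <- nrow(ext) + 1
  asc <- logical(n_seg)
  for (s in seq_len(n_seg)) {
    if (s <= nrow(ext)) {
      asc[s] <- ext$side[s] == "min"      # ends at a minimum => beta rising
    } else {
      asc[s] <- ext$side[nrow(ext)] == "max"  # after a maximum beta rises
    }
  }
  base <- 90 * seg
  theta <- ifelse(asc[seg + 1], base + beta, base + 90 - beta)
  valid <- rep(TRUE, n)
  valid[ext$frame[ext$kind == "local"]] <- FALSE
  if (enforce_monotone) theta <- cummax(theta)
  ext$theta_nominal <- 90 * seq_len(nrow(ext))
  out <- tibble(frame = curve$frame, minor_len = l, beta_deg = beta,
                theta_deg = theta, valid = valid, segment = seg)
  attr(out, "extrema") <- ext
  attr(out, "max_rolling_angle") <- max(theta[valid]) - min(theta[valid])
  attr(out, "b_semi") <- b_semi
  attr(out, "c_semi") <- c_semi
  class(out) <- c("angle_series", class(out))
  out
}

#' Check the single-axis-rotation assumption
#'
#' The recovery model assumes a rigid rotation about a single axis in the
#' image plane, in which case the projected major axis is constant. Flags a
#' violation when the coefficient of variation of the major-axis lengths
#' exceeds `max_cv`.
#'
#' @param major_len Vector of per-frame major-axis lengths (um).
#' @param max_cv Maximum allowed std/mean (default 0.03).
#' @return Logical: TRUE if the assumption holds. Warns otherwise.
#' @export
check_major_axis_constancy <- function(major_len, max_cv = 0.03) {
  cv <- sd_pop(major_len) / mean(major_len)
  ok <- cv <= max_cv
  if (!ok)
    warn(sprintf("major axis varies (cv = %.3f > %.3f): single in-plane rotation axis assumption violated",
                 cv, max_cv))
  ok
}

#' Recover rolling angles for a sequence of phase maps
#'
#' Full per-sequence angle tracking: segment each frame
#' ([segment_ellipse()]), align and centre it ([align_and_center()]), build
#' the minor-axis curve ([build_minor_axis_curve()]) and unwrap the folded
#' angles ([unwrap_angles()]).
#'
#' @param phase_maps List of [phase_map()]s (ROI sequence of one nucleus).
#' @param threshold,threshold_frac Passed to [segment_ellipse()].
#' @param smooth_window,global_tol Passed to [build_minor_axis_curve()].
#' @param ... Passed to [unwrap_angles()].
#' @return List with `angles` (the [unwrap_angles()] `angle_series`),
#'   `curve`, `aligned` (list of aligned [phase_map()]s), `ellipses`.
#' @export
recover_rolling_angles <- function(phase_maps, threshold = NULL,
                                   threshold_frac = 0.1, smooth_window = 3,
                                   global_tol = 0.02, ...) {
  segs <- purrr::map(phase_maps, segment_ellipse, threshold = threshold,
                     threshold_frac = threshold_frac)
  ellipses <- purrr::map(segs, "ellipse")
  aligned <- purrr::map2(phase_maps, ellipses, align_and_center)
  curve <- build_minor_axis_curve(ellipses, smooth_window = smooth_window,
                                  global_tol = global_tol)
  check_major_axis_constancy(dplyr::bind_rows(ellipses)$major_len)
  angles <- unwrap_angles(curve, ...)
  list(angles = angles, curve = curve, aligned = aligned, ellipses = ellipses)
}
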