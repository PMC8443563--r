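#' Centroid of a binary mask
#'
#' Intensity-unweighted centre of mass of the mask pixels, in micrometres
#' (0-based pixel centres times `pixel_size`). Set `weights` to a matrix
#' (e.g. the phase map) for a weighted centroid.
#'
#' @param mask Logical or 0/1 matrix.
#' @param pixel_size Micrometres per pixel.
#' @param weights Optional non-negative weight matrix of the same shape.
#' @return Named numeric `c(x, y)` in micrometres.
#' @export
centroid <- function(mask, pixel_size, weights = NULL) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) abort("mask is empty")
  w <- if (is.null(weights)) rep(1, nrow(idx)) else {
    stopifnot(identical(dim(weights), dim(mask)))
    weights[mask > 0]
  }
  c(x = sum((idx[, 2] - 1) * w) / sum(w) * pixel_size,
    y = sum((idx[, 1] - 1) * w) / sum(w) * pixel_size)
}

#' Projected area and in-plane orientation of a mask
#'
#' Area is the pixel count times `pixel_size^2`. Orientation is the angle of
#' the major axis of the equivalent ellipse with respect to the x axis,
#' \eqn{\tfrac12 \mathrm{atan2}(2\mu_{11}, \mu_{20} - \mu_{02})} from central
#' second moments, mapped to (-90, 90] degrees. Isotropic masks (circles) get
#' orientation 0 by tie-break; a single-pixel mask warns and returns 0.
#'
#' @inheritParams centroid
#' @return Named numeric `c(area, orientation_deg)` (area in um^2).
#' @export
area_and_orientation <- function(mask, pixel_size) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) abort("mask is empty")
  area <- nrow(idx) * pixel_size^2
  if (nrow(idx) == 1) {
    warn("single-pixel mask: orientation set to 0")
    return(c(area = area, orientation_deg = 0))
  }
  x <- idx[, 2] - mean(idx[, 2])
  y <- idx[, 1] - mean(idx[, 1])
  mu20 <- mean(x^2); mu02 <- mean(y^2); mu11 <- mean(x * y)
  if (abs(mu20 - mu02) < 1e-9 && abs(mu11) < 1e-9) {
    ang <- 0  # isotropic tie-break
  } else {
    ang <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  }
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  c(area = area, orientation_deg = ang)
}

#' Axial position of a nucleus by Tamura refocusing
#'
#' Runs [autofocus()] on the full field with the focus metric restricted to
#' the region of interest (so one nucleus drives the focus), and reports the
#' best-focus offset relative to the reference plane z0.
#'
#' @param field A [complex_field()].
#' @param roi Logical matrix marking the nucleus.
#' @param z_range Length-2 search range (um).
#' @param z0 Reference axial position (um) subtracted from the result.
#' @param ... Passed to [autofocus()].
#' @return z_N in micrometres (relative to z0).
#' @export
track_axial <- function(field, roi, z_range, z0 = 0, ...) {
  if (!any(roi > 0)) abort("roi is empty")
  zf <- autofocus(field, z_range, roi = roi, ...)
  as.numeric(zf) - z0
}

#' Per-frame 3D track table for a nucleus sequence
#'
#' Convenience wrapper combining [centroid()], [area_and_orientation()] and
#' (optionally) [track_axial()] over a sequence of frames into a tidy track
#' table.
#'
#' @param nucleus_masks List of binary masks, one per frame.
#' @param cell_masks Optional list of cell masks (for relative positions).
#' @param pixel_size Micrometres per pixel.
#' @param times Optional frame times (hours).
#' @param fields Optional list of [complex_field()]s for axial tracking.
#' @param z_range,z0 Passed to [track_axial()] when `fields` is given.
#' @return Tibble with one row per frame: frame, time, x_n, y_n, x_c, y_c,
#'   rel_x, rel_y, z_n, area, orientation_deg.
#' @export
track_nuclei <- function(nucleus_masks, cell_masks = NULL, pixel_size,
                         times = NULL, fields = NULL, z_range = c(-50, 50),
                         z0 = 0) {
  n <- length(nucleus_masks)
  rows <- purrr::map(seq_len(n), function(i) {
    cn <- centroid(nucleus_masks[[i]], pixel_size)
    ao <- area_and_orientation(nucleus_masks[[i]], pixel_size)
    cc <- if (!is.null(cell_masks)) centroid(cell_masks[[i]], pixel_size)
          else c(x = NA_real_, y = NA_real_)
    zn <- if (!is.null(fields))
      track_axial(fields[[i]], nucleus_masks[[i]], z_range, z0)
    else NA_real_
    tibble(frame = i,
           time = if (is.null(times)) NA_real_ else times[i],
           x_n = cn[["x"]], y_n = cn[["y"]],
           x_c = cc[["x"]], y_c = cc[["y"]],
           rel_x = cn[["x"]] - cc[["x"]], rel_y = cn[["y"]] - cc[["y"]],
           z_n = zn, area = ao[["area"]],
           orientation_deg = ao[["orientation_deg"]])
  })
  dplyr::bind_rows(rows)
}
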