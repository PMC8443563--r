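#' @importFrom stats fft sd median quantile approx density coef lm optimize
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

#' Quantitative phase map
#'
#' A 2D map of optical phase delay \eqn{\varphi(x,y) = (2\pi/\lambda)\int
#' \Delta n\, dz} through a transparent specimen, in radians, together with
#' the optics metadata needed downstream.
#'
#' Matrix convention throughout the package: rows index the vertical image
#' coordinate y, columns the horizontal coordinate x; pixel centres sit at
#' 0-based integer indices times `pixel_size`.
#'
#' @param phase Numeric matrix of phase values (radians).
#' @param pixel_size Pixel size in the image plane (micrometres).
#' @param wavelength Illumination wavelength (micrometres).
#' @param frame_time Optional acquisition time of the frame (hours).
#' @return An object of class `phase_map`.
#' @export
phase_map <- function(phase, pixel_size, wavelength, frame_time = NA_real_) {
  stopifnot(is.matrix(phase))
  if (!all(is.finite(phase))) abort("phase must be finite")
  if (!is.numeric(pixel_size) || pixel_size <= 0) abort("pixel_size must be > 0")
  if (!is.numeric(wavelength) || wavelength <= 0) abort("wavelength must be > 0")
  structure(
    list(phase = phase, pixel_size = pixel_size, wavelength = wavelength,
         frame_time = frame_time),
    class = "phase_map"
  )
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %d x %d px, %.3g um/px, lambda %.4g um, range [%.3g, %.3g] rad\n",
              nrow(x$phase), ncol(x$phase), x$pixel_size, x$wavelength,
              min(x$phase), max(x$phase)))
  invisible(x)
}

#' Off-axis digital hologram
#'
#' Real non-negative intensity frame \eqn{H = |R + O|^2} recorded with a
#' tilted reference beam, plus optics metadata.
#'
#' @param intensity Non-negative numeric matrix.
#' @param pixel_size,wavelength Micrometres.
#' @param carrier_hint Optional length-2 carrier frequency (cycles/pixel,
#'   c(fx, fy)) used to seed sideband detection.
#' @return An object of class `hologram`.
#' @export
hologram <- function(intensity, pixel_size, wavelength, carrier_hint = NULL) {
  stopifnot(is.matrix(intensity))
  if (any(intensity < 0)) abort("hologram intensity must be non-negative")
  if (pixel_size <= 0) abort("pixel_size must be > 0")
  structure(
    list(intensity = intensity, pixel_size = pixel_size,
         wavelength = wavelength, carrier_hint = carrier_hint),
    class = "hologram"
  )
}

#' Complex optical field
#'
#' Demodulated object field \eqn{R^*O} or a propagated version of it.
#'
#' @param values Complex matrix.
#' @param pixel_size,wavelength Micrometres.
#' @param z_offset Propagation offset from the acquisition plane (micrometres).
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(values, pixel_size, wavelength, z_offset = 0) {
  stopifnot(is.matrix(values))
  if (!all(is.finite(Re(values)) & is.finite(Im(values)))) abort("field values must be finite")
  structure(
    list(values = values, pixel_size = pixel_size, wavelength = wavelength,
         z_offset = z_offset),
    class = "complex_field"
  )
}

#' Refractive-index tomogram
#'
#' 3D refractive-index volume reconstructed by filtered back-projection.
#' The array is indexed `[y, z, x]`: the rotation axis x (shared major axis
#' of the aligned projections) is the third dimension, and each `[, , i]`
#' slab is the reconstructed (y, z) slice for one position along it.
#'
#' @param ri 3D numeric array of refractive index, `[y, z, x]`.
#' @param voxel_size Isotropic voxel size (micrometres).
#' @param background_ri Background (immersion) refractive index.
#' @param ri_raw Optional unclipped volume.
#' @return An object of class `tomogram`.
#' @export
tomogram <- function(ri, voxel_size, background_ri, ri_raw = NULL) {
  stopifnot(length(dim(ri)) == 3)
  if (voxel_size <= 0) abort("voxel_size must be > 0")
  structure(
    list(ri = ri, voxel_size = voxel_size, background_ri = background_ri,
         ri_raw = ri_raw),
    class = "tomogram"
  )
}

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x$ri)
  cat(sprintf("<tomogram> %d x %d x %d voxels (y,z,x), %.3g um/voxel, n_bg = %.4g, RI range [%.4f, %.4f]\n",
              d[1], d[2], d[3], x$voxel_size, x$background_ri,
              min(x$ri), max(x$ri)))
  invisible(x)
}

# centred physical coordinates of pixel centres along an axis of n pixels
axis_coords <- function(n, pixel_size) {
  (seq_len(n) - 1 - (n - 1) / 2) * pixel_size
}

# population standard deviation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# fft frequencies in cycles per sample (like numpy fftfreq)
fft_freq <- function(n) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / n
}

# bilinear sampling of matrix `img` at fractional 0-based (row, col) positions;
# outside the grid returns `fill`
bilinear_sample <- function(img, r, c, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  inside <- r0 >= 0 & c0 >= 0 & r0 <= nr - 2 & c0 <= nc - 2
  out <- rep(fill, length(r))
  if (any(inside)) {
    r0i <- r0[inside]; c0i <- c0[inside]
    fri <- fr[inside]; fci <- fc[inside]
    i00 <- r0i + 1 + c0i * nr
    v <- img[i00]       * (1 - fri) * (1 - fci) +
         img[i00 + 1]   * fri       * (1 - fci) +
         img[i00 + nr]  * (1 - fri) * fci +
         img[i00 + nr + 1] * fri    * fci
    out[inside] <- v
  }
  out
}
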