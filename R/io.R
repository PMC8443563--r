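# TIFF storage note: the tiff package stores samples normalized to [0, 1]
# (32-bit depth). Stacks are therefore written with a global affine scaling
# (offset, scale) recorded in a small JSON sidecar "<path>.scale.json" and
# undone transparently on read; at 32 bits the quantization is ~2e-10 of the
# data range, far below any optical phase noise.

write_scaled_stack <- function(mats, path) {
  lo <- min(vapply(mats, min, numeric(1)))
  hi <- max(vapply(mats, max, numeric(1)))
  scale <- if (hi > lo) hi - lo else 1
  scaled <- lapply(mats, function(m) (m - lo) / scale)
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, reduce = FALSE,
                  compression = "none")
  jsonlite::write_json(list(offset = lo, scale = scale),
                       paste0(path, ".scale.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_scaled_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  side <- paste0(path, ".scale.json")
  if (file.exists(side)) {
    sc <- jsonlite::read_json(side, simplifyVector = TRUE)
    pages <- lapply(pages, function(m) m * sc$scale + sc$offset)
  }
  pages
}

#' Write a stack of phase maps as multi-page 32-bit TIFF
#'
#' Values are affinely normalized for storage; the offset and scale are kept
#' in a `<path>.scale.json` sidecar and undone by [read_phase_stack()].
#'
#' @param phase_maps List of [phase_map()]s (or numeric matrices).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_phase_stack <- function(phase_maps, path) {
  mats <- lapply(phase_maps, function(p)
    if (inherits(p, "phase_map")) p$phase else p)
  write_scaled_stack(mats, path)
}

#' Read a multi-page TIFF stack as phase maps
#'
#' @param path TIFF file (single or multi-page); a `<path>.scale.json`
#'   sidecar, if present, restores the physical value range.
#' @param pixel_size,wavelength Optics metadata (um).
#' @param times Optional per-frame times (hours).
#' @return List of [phase_map()]s.
#' @export
read_phase_stack <- function(path, pixel_size, wavelength, times = NULL) {
  pages <- read_scaled_stack(path)
  purrr::imap(pages, function(m, i)
    phase_map(m, pixel_size, wavelength,
              frame_time = if (is.null(times)) NA_real_ else times[[i]]))
}

#' Write a tomogram to disk
#'
#' The RI volume is written as a multi-page 32-bit TIFF (one page per slice
#' along x, affinely normalized with a scale sidecar) plus a JSON metadata
#' sidecar (`<path>.json`) holding voxel size, background RI and dimensions.
#'
#' @param tomo A [tomogram()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_tomogram <- function(tomo, path) {
  d <- dim(tomo$ri)
  pages <- lapply(seq_len(d[3]), function(ix) tomo$ri[, , ix])
  write_scaled_stack(pages, path)
  meta <- list(dim = d, voxel_size = tomo$voxel_size,
               background_ri = tomo$background_ri, order = "y,z,x")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a tomogram written by [write_tomogram()]
#'
#' @param path TIFF path (expects the `<path>.json` sidecar).
#' @return A [tomogram()].
#' @export
read_tomogram <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- read_scaled_stack(path)
  ri <- array(0, dim = meta$dim)
  for (ix in seq_along(pages)) ri[, , ix] <- pages[[ix]]
  tomogram(ri, meta$voxel_size, meta$background_ri)
}
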