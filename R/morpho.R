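#' Segment the nucleus in a tomogram
#'
#' Thresholds the volume at `background_ri + delta`, keeps the largest 3D
#' connected component (6-connectivity) and applies a light morphological
#' closing (per axial slice).
#'
#' @param tomo A [tomogram()].
#' @param delta RI excess over background defining "nucleus" voxels
#'   (default 0.005).
#' @param closing_size Brush diameter (voxels) of the 2D closing applied to
#'   each slice along x; 0 disables (default 3).
#' @return Logical 3D array (same dims as `tomo$ri`), with attribute
#'   `volume` in um^3.
#' @export
segment_nucleus_mask <- function(tomo, delta = 0.005, closing_size = 3) {
  stopifnot(inherits(tomo, "tomogram"))
  bw <- tomo$ri > tomo$background_ri + delta
  if (!any(bw)) abort("no voxels above background + delta: nucleus not found")
  if (closing_size > 0) {
    brush <- EBImage::makeBrush(closing_size, shape = "disc")
    for (ix in seq_len(dim(bw)[3])) {
      bw[, , ix] <- EBImage::closing(bw[, , ix] * 1, brush) > 0
    }
  }
  lab <- label_volume(bw)
  tab <- tabulate(lab[lab > 0])
  if (length(tab) == 0) abort("no voxels above background + delta: nucleus not found")
  mask <- lab == which.max(tab)
  attr(mask, "volume") <- sum(mask) * tomo$voxel_size^3
  mask
}

# 3D connected-component labelling (6-connectivity): per-slice 2D labelling
# (EBImage::bwlabel) merged across adjacent slices with union-find
label_volume <- function(bw) {
  d <- dim(bw)
  labs <- array(0L, d)
  offset <- 0L
  n_per_slice <- integer(d[3])
  for (ix in seq_len(d[3])) {
    sl <- EBImage::bwlabel(bw[, , ix] * 1)
    m <- max(sl)
    sl[sl > 0] <- sl[sl > 0] + offset
    labs[, , ix] <- sl
    n_per_slice[ix] <- m
    offset <- offset + as.integer(m)
  }
  if (offset == 0L) return(labs)
  parent <- seq_len(offset)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  for (ix in seq_len(d[3] - 1)) {
    a <- labs[, , ix]; b <- labs[, , ix + 1]
    both <- a > 0 & b > 0
    if (any(both)) {
      pairs <- unique(cbind(a[both], b[both]))
      for (r in seq_len(nrow(pairs))) union(pairs[r, 1], pairs[r, 2])
    }
  }
  roots <- vapply(seq_len(offset), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  pos <- labs > 0
  labs[pos] <- relab[labs[pos]]
  labs
}

#' Segment the nucleolus by its refractive-index interval
#'
#' Within the nucleus mask, finds the antimode (histogram valley) of the RI
#' distribution between the nucleoplasm mode and the high-RI mode and
#' thresholds above it; when no valley is found, falls back to an
#' upper-quantile threshold. Keeps the largest connected component and
#' reports a valley-depth unimodality check of the segmented distribution.
#'
#' @param tomo A [tomogram()].
#' @param nucleus_mask Logical 3D mask from [segment_nucleus_mask()].
#' @param fallback_quantile Upper quantile used when no valley is found
#'   (default 0.9).
#' @param min_voxels Minimum nucleolus size in voxels (default 30).
#' @param min_mode_separation Minimum RI distance between the nucleoplasm
#'   mode and a candidate high-RI mode (default 0.004).
#' @param min_valley_depth Minimum relative dip of the valley below the
#'   smaller of the two modes for the valley to be trusted (default 0.1).
#' @return Logical 3D mask with attributes `volume` (um^3), `threshold`,
#'   `valley_found`, `valley_depth` (relative dip between the two modes; NA
#'   when no valley).
#' @export
segment_nucleolus <- function(tomo, nucleus_mask, fallback_quantile = 0.9,
                              min_voxels = 30, min_mode_separation = 0.004,
                              min_valley_depth = 0.1) {
  if (!any(nucleus_mask)) abort("nucleus mask is empty")
  ri <- tomo$ri[nucleus_mask]
  den <- density(ri, n = 512)
  dy <- diff(den$y)
  s <- sign(dy)
  turn <- which(s[-1] != s[-length(s)] & s[-length(s)] != 0) + 1
  peaks <- turn[s[pmax(turn - 1, 1)] > 0]       # rising-then-falling = maxima
  valleys <- turn[s[pmax(turn - 1, 1)] < 0]
  thr <- NA_real_; valley_found <- FALSE; valley_depth <- NA_real_
  main <- which.max(den$y)
  high <- peaks[den$x[peaks] > den$x[main] + min_mode_separation]
  if (length(high) > 0) {
    hp <- high[which.max(den$y[high])]
    between <- valleys[valleys > main & valleys < hp]
    if (length(between) > 0) {
      v <- between[which.min(den$y[between])]
      depth <- 1 - den$y[v] / min(den$y[main], den$y[hp])
      if (depth >= min_valley_depth) {
        thr <- den$x[v]
        valley_found <- TRUE
        valley_depth <- depth
      }
    }
  }
  if (!valley_found) thr <- quantile(ri, fallback_quantile, names = FALSE)
  bw <- tomo$ri > thr & nucleus_mask
  if (sum(bw) < min_voxels)
    abort("no nucleolus resolved: high-RI component below minimum voxel count")
  lab <- label_volume(bw)
  tab <- tabulate(lab[lab > 0])
  mask <- lab == which.max(tab)
  if (sum(mask) < min_voxels)
    abort("no nucleolus resolved: high-RI component below minimum voxel count")
  attr(mask, "volume") <- sum(mask) * tomo$voxel_size^3
  attr(mask, "threshold") <- thr
  attr(mask, "valley_found") <- valley_found
  attr(mask, "valley_depth") <- valley_depth
  mask
}

#' Sphere-equivalent radius of a volume
#'
#' \eqn{r = (3V / 4\pi)^{1/3}}: radius of the sphere with the same volume.
#'
#' @param volume Volume(s) in um^3.
#' @return Radius in um.
#' @export
equivalent_radius <- function(volume) {
  if (any(volume <= 0)) abort("volume must be > 0")
  (3 * volume / (4 * pi))^(1 / 3)
}

#' Principal axis lengths of a 3D mask
#'
#' Eigen-decomposition of the voxel-coordinate covariance; full axis lengths
#' are `2 * sqrt(5 * eigenvalue)`, exact for a uniform solid ellipsoid.
#' Returned in descending order, micrometres.
#'
#' @param mask Logical 3D array.
#' @param voxel_size Um per voxel (isotropic).
#' @return Numeric length-3 `(p1, p2, p3)`, descending.
#' @export
principal_axes <- function(mask, voxel_size) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 10) abort("mask too small (< 10 voxels) for principal axes")
  X <- sweep(idx, 2, colMeans(idx)) * voxel_size
  C <- crossprod(X) / nrow(X)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-9 * max(ev)) abort("degenerate (coplanar) mask")
  sort(2 * sqrt(5 * ev), decreasing = TRUE)
}

#' Refractive-index statistics over a mask
#'
#' @param tomo A [tomogram()].
#' @param mask Logical array matching `tomo$ri`.
#' @return Named numeric: mean, sd (population), min, max.
#' @export
ri_statistics <- function(tomo, mask) {
  if (!any(mask)) abort("mask is empty")
  v <- tomo$ri[mask]
  c(mean = mean(v), sd = sd_pop(v), min = min(v), max = max(v))
}

#' Dry mass from mean refractive index and volume
#'
#' \deqn{m_d = (\bar n - n_w) V / \alpha} with \eqn{n_w} the refractive index
#' of water and \eqn{\alpha} the refraction increment of dry matter
#' (0.2 ml/g = 0.2 um^3/pg for protein/DNA), giving picograms from um^3.
#' A negative result (mean RI below water) is allowed but flagged.
#'
#' @param ri_mean Mean refractive index of the object.
#' @param volume_um3 Object volume (um^3).
#' @param n_w Refractive index of water (default 1.334).
#' @param alpha Refraction increment (um^3/pg; default 0.2).
#' @return Dry mass in pg.
#' @export
dry_mass <- function(ri_mean, volume_um3, n_w = 1.334, alpha = 0.2) {
  if (any(volume_um3 <= 0)) abort("volume must be > 0")
  if (alpha <= 0) abort("alpha must be > 0")
  md <- (ri_mean - n_w) * volume_um3 / alpha
  if (any(md < 0)) warn("negative dry mass: mean RI below the RI of water")
  md
}

#' Nucleolar-to-nuclear volume ratio
#'
#' @param v_nucleolus,v_nucleus Volumes (um^3), `0 < v_nucleolus < v_nucleus`.
#' @return Ratio in percent.
#' @export
volume_ratio <- function(v_nucleolus, v_nucleus) {
  if (any(v_nucleolus <= 0) || any(v_nucleus <= 0))
    abort("volumes must be > 0")
  if (any(v_nucleolus >= v_nucleus))
    abort("nucleolar volume must be smaller than nuclear volume")
  100 * v_nucleolus / v_nucleus
}

#' Full sub-nuclear quantification of a tomogram
#'
#' Segments nucleus and nucleolus and assembles the standard per-nucleus
#' metrics record: volumes, equivalent radii, principal axes, RI statistics,
#' dry masses and the nucleolar-nuclear volume ratio.
#'
#' @param tomo A [tomogram()].
#' @param n_w,alpha Dry-mass constants (see [dry_mass()]).
#' @param delta Passed to [segment_nucleus_mask()].
#' @param ... Passed to [segment_nucleolus()].
#' @return One-row tibble of class `nuclear_metrics`.
#' @export
nuclear_metrics <- function(tomo, n_w = 1.334, alpha = 0.2, delta = 0.005,
                            ...) {
  nmask <- segment_nucleus_mask(tomo, delta = delta)
  smask <- segment_nucleolus(tomo, nmask, ...)
  vn <- attr(nmask, "volume"); vs <- attr(smask, "volume")
  pn <- principal_axes(nmask, tomo$voxel_size)
  ps <- principal_axes(smask, tomo$voxel_size)
  rn <- ri_statistics(tomo, nmask)
  rs <- ri_statistics(tomo, smask)
  out <- tibble(
    nuclear_volume = vn,
    nuclear_equiv_radius = equivalent_radius(vn),
    nuclear_p1 = pn[1], nuclear_p2 = pn[2], nuclear_p3 = pn[3],
    nuclear_ri_mean = rn[["mean"]], nuclear_ri_sd = rn[["sd"]],
    nuclear_ri_min = rn[["min"]], nuclear_ri_max = rn[["max"]],
    nuclear_dry_mass = dry_mass(rn[["mean"]], vn, n_w, alpha),
    nucleolar_volume = vs,
    nucleolar_equiv_radius = equivalent_radius(vs),
    nucleolar_p1 = ps[1], nucleolar_p2 = ps[2], nucleolar_p3 = ps[3],
    nucleolar_ri_mean = rs[["mean"]], nucleolar_ri_sd = rs[["sd"]],
    nucleolar_ri_min = rs[["min"]], nucleolar_ri_max = rs[["max"]],
    nucleolar_dry_mass = dry_mass(rs[["mean"]], vs, n_w, alpha),
    volume_ratio_percent = volume_ratio(vs, vn),
    n_w = n_w, alpha = alpha
  )
  class(out) <- c("nuclear_metrics", class(out))
  out
}

#' Per-nucleus metrics table with a mean +- sd summary
#'
#' Binds per-nucleus metric records and appends a summary row per field
#' (mean and sd over the available records). Per-record RI statistics use the
#' population convention; the summary across nuclei uses the sample (n - 1)
#' standard deviation, as appropriate for a sample of nuclei.
#'
#' @param metrics A `nuclear_metrics` record, or a list of them.
#' @return Tibble in long layout: metric, one column per nucleus, mean, sd,
#'   n (number of non-missing records per metric).
#' @export
report_table <- function(metrics) {
  if (inherits(metrics, "nuclear_metrics")) metrics <- list(metrics)
  if (length(metrics) < 1) abort("need at least one metrics record")
  wide <- dplyr::bind_rows(lapply(seq_along(metrics), function(i)
    dplyr::mutate(as_tibble(metrics[[i]]), .nucleus = paste0("nucleus_", i))))
  long <- tidyr::pivot_longer(wide, -".nucleus", names_to = "metric",
                              values_to = "value")
  stats <- long |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = if (sum(!is.na(.data$value)) > 1) sd(.data$value, na.rm = TRUE) else 0,
      n = sum(!is.na(.data$value)), .groups = "drop")
  vals <- tidyr::pivot_wider(long, names_from = ".nucleus",
                             values_from = "value")
  out <- dplyr::left_join(vals, stats, by = "metric")
  # preserve the metric order of the record
  out[match(names(as_tibble(metrics[[1]])), out$metric), ]
}
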