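#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a logistic contrast fit
#'
#' @param x A [fit_logistic()] result.
#' @param ... Unused.
#' @return Tibble with one row per parameter (A, B, k, t0): estimate,
#'   std.error, statistic, p.value.
#' @export
tidy.logistic_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' One-row summary of a logistic contrast fit
#'
#' @param x A [fit_logistic()] result.
#' @param ... Unused.
#' @return Tibble: t_plasmolysis, growth_rate, sigma, r.squared, nobs.
#' @export
glance.logistic_fit <- function(x, ...) {
  r <- stats::residuals(x$fit)
  y <- x$series$contrast_norm
  if (x$normalize == "after") y <- x$series$contrast_raw
  tibble(t_plasmolysis = x$params$t0,
         growth_rate = x$params$k,
         sigma = sqrt(mean(r^2)),
         r.squared = 1 - sum(r^2) / sum((y - mean(y))^2),
         nobs = nrow(x$series))
}

#' Tidy an angle series
#'
#' @param x An `angle_series` from [unwrap_angles()].
#' @param ... Unused.
#' @return The underlying tibble (frame, minor_len, beta_deg, theta_deg,
#'   valid, segment).
#' @export
tidy.angle_series <- function(x, ...) {
  as_tibble(unclass(x)[seq_along(x)])
}

#' One-row summary of an angle series
#'
#' @param x An `angle_series`.
#' @param ... Unused.
#' @return Tibble: n_frames, n_valid, n_extrema, n_local_extrema,
#'   max_rolling_angle.
#' @export
glance.angle_series <- function(x, ...) {
  ext <- attr(x, "extrema")
  tibble(n_frames = nrow(x), n_valid = sum(x$valid),
         n_extrema = nrow(ext),
         n_local_extrema = sum(ext$kind == "local"),
         max_rolling_angle = attr(x, "max_rolling_angle"))
}
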