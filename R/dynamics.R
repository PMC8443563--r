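#' Global image contrast of a phase map
#'
#' Sum of the modulus of the discrete Laplacian (5-point stencil
#' `[0,1,0; 1,-4,1; 0,1,0]`) over interior pixels, optionally restricted to a
#' region of interest. This is the scalar whose growth during dehydration is
#' fitted by a logistic in [fit_logistic()].
#'
#' @param qpm A [phase_map()] or a plain numeric matrix.
#' @param roi Optional logical matrix of the same shape; only interior pixels
#'   where `roi` is `TRUE` contribute.
#' @return Scalar contrast (radians, arbitrary units).
#' @export
global_contrast <- function(qpm, roi = NULL) {
  m <- if (inherits(qpm, "phase_map")) qpm$phase else qpm
  stopifnot(is.matrix(m))
  if (!all(is.finite(m))) abort("phase map must be finite")
  n <- nrow(m); p <- ncol(m)
  if (n < 3 || p < 3) abort("phase map too small for an interior Laplacian")
  lap <- m[2:(n - 1), 1:(p - 2)] + m[2:(n - 1), 3:p] +
    m[1:(n - 2), 2:(p - 1)] + m[3:n, 2:(p - 1)] -
    4 * m[2:(n - 1), 2:(p - 1)]
  if (!is.null(roi)) {
    stopifnot(identical(dim(roi), dim(m)))
    ri <- roi[2:(n - 1), 2:(p - 1)]
    if (!any(ri)) abort("roi is empty")
    return(sum(abs(lap[ri])))
  }
  sum(abs(lap))
}

#' Fit a logistic to a dehydration contrast series
#'
#' Min-max normalizes the contrast to `[0, 1]` and fits the four-parameter
#' logistic \eqn{L(t) = A + (B - A) / (1 + e^{-k (t - t_0)})} by
#' Levenberg-Marquardt least squares ([minpack.lm::nlsLM]). The midpoint
#' \eqn{t_0} is where the fitted derivative peaks, i.e. the plasmolysis time
#' (see [detect_plasmolysis()]).
#'
#' @param times Strictly increasing times (hours).
#' @param contrast Raw global contrast values (same length).
#' @param normalize `"before"` (default) min-max normalizes then fits;
#'   `"after"` fits the raw values and reports normalized curves afterwards.
#' @return An object of class `logistic_fit`: list with `params` (A, B, k,
#'   t0), `series` (tibble: time, contrast_raw, contrast_norm, fitted,
#'   derivative), and the underlying `nls` fit. Supports [generics::tidy()]
#'   and [generics::glance()].
#' @export
fit_logistic <- function(times, contrast, normalize = c("before", "after")) {
  normalize <- match.arg(normalize)
  stopifnot(length(times) == length(contrast))
  if (length(times) < 6) abort("need at least 6 time points")
  if (any(diff(times) <= 0)) abort("times must be strictly increasing")
  rng <- max(contrast) - min(contrast)
  if (rng == 0) abort("contrast is constant; nothing to fit")
  norm <- (contrast - min(contrast)) / rng
  y <- if (normalize == "before") norm else contrast
  # initialization from data quantiles
  a0 <- min(y); b0 <- max(y)
  t0_0 <- times[which.min(abs(y - (a0 + b0) / 2))]
  dy <- diff(y) / diff(times)
  k0 <- 4 * max(abs(dy)) / (b0 - a0) * sign(dy[which.max(abs(dy))])
  if (!is.finite(k0) || k0 == 0) k0 <- 1
  dat <- data.frame(t = times, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A + (B - A) / (1 + exp(-k * (t - t0))),
                      data = dat,
                      start = list(A = a0, B = b0, k = k0, t0 = t0_0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort(paste0("logistic fit did not converge: ",
                                     conditionMessage(e)))
  )
  p <- as.list(coef(fit))
  lfun <- function(t) p$A + (p$B - p$A) / (1 + exp(-p$k * (t - p$t0)))
  dfun <- function(t) {
    e <- exp(-p$k * (t - p$t0))
    (p$B - p$A) * p$k * e / (1 + e)^2
  }
  fitted_y <- lfun(times)
  fitted_norm <- if (normalize == "before") fitted_y else
    (fitted_y - min(contrast)) / rng
  structure(
    list(params = p,
         normalize = normalize,
         series = tibble(time = times, contrast_raw = contrast,
                         contrast_norm = norm, fitted = fitted_norm,
                         derivative = dfun(times)),
         derivative_fun = dfun,
         fit = fit),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> A = %.4g, B = %.4g, k = %.4g /h, t0 = %.4g h (n = %d)\n",
              x$params$A, x$params$B, x$params$k, x$params$t0,
              nrow(x$series)))
  invisible(x)
}

#' Detect the plasmolysis time from a fitted contrast logistic
#'
#' The time derivative of the logistic peaks at its midpoint, so the
#' plasmolysis (membrane-detachment) time is the fitted \eqn{t_0}. A
#' decreasing fit (k < 0) still returns \eqn{t_0} but warns, since the
#' derivative is then a negative-going trough.
#'
#' @param fit A [fit_logistic()] result.
#' @return List with `t_plasmolysis` (hours) and `derivative` (tibble: time,
#'   derivative) for plotting.
#' @export
detect_plasmolysis <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (fit$params$k < 0)
    warn("fitted logistic is decreasing (k < 0); derivative peak is a trough")
  list(t_plasmolysis = fit$params$t0,
       derivative = fit$series[, c("time", "derivative")])
}

#' Protoplast / cell area-ratio trend
#'
#' Computes the percentage ratio 100 * A_P / A_C per frame from protoplast and
#' cell masks (or pre-computed areas) and fits an ordinary least-squares line
#' to the post-plasmolysis frames; the slope (% per hour) quantifies the
#' shrinkage rate.
#'
#' @param times Frame times (hours).
#' @param protoplast Either a list of logical/binary masks or a numeric vector
#'   of protoplast areas.
#' @param cell Same form, for the whole cell.
#' @param t_plasmolysis Plasmolysis time (hours); the line is fitted on
#'   frames with `time >= t_plasmolysis`.
#' @return An object of class `area_trend`: tibble (time, ratio_percent,
#'   post_plasmolysis) with attributes `slope` (%/h), `intercept` (%) and
#'   `t_plasmolysis`.
#' @export
area_ratio_trend <- function(times, protoplast, cell, t_plasmolysis) {
  as_area <- function(x) {
    if (is.list(x)) vapply(x, function(m) sum(m > 0), numeric(1)) else as.numeric(x)
  }
  ap <- as_area(protoplast); ac <- as_area(cell)
  stopifnot(length(times) == length(ap), length(ap) == length(ac))
  if (any(ac <= 0)) abort("cell area must be > 0 in every frame")
  ratio <- 100 * ap / ac
  post <- times >= t_plasmolysis
  if (sum(post) < 3) abort("need at least 3 post-plasmolysis frames for the linear fit")
  fit <- lm(ratio[post] ~ times[post])
  out <- tibble(time = times, ratio_percent = ratio, post_plasmolysis = post)
  attr(out, "slope") <- unname(coef(fit)[2])
  attr(out, "intercept") <- unname(coef(fit)[1])
  attr(out, "t_plasmolysis") <- t_plasmolysis
  class(out) <- c("area_trend", class(out))
  out
}
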