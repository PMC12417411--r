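# CO2-dependence of the respiratory fluxes: polynomial / linear trends.

#' Fit a polynomial or linear trend of a flux against ambient CO2
#'
#' Ordinary least squares on the raw polynomial basis
#' \eqn{y = \beta_0 + \beta_1 x + \dots + \beta_d x^d}.  Photorespiration and
#' day respiration are unimodal in ambient CO2, so the default is the
#' minimal unimodal form (degree 2); dark respiration declines linearly
#' (`kind = "linear"`).  Requires at least `degree + 2` points so that a
#' residual degree of freedom remains (exact interpolation is refused).
#'
#' @param x CO2 levels (\eqn{\mu}mol mol\eqn{^{-1}}).
#' @param y Flux means at those levels.
#' @param kind `"polynomial"` or `"linear"` (forces degree 1).
#' @param degree Polynomial degree \eqn{\ge 1}.
#' @return Object of class `trend_fit`: `kind`, `degree`, `coefficients`
#'   (ascending power), `r2`, `x_at_extremum` (derivative root inside the
#'   data range; `NA` when none), `n`, and the underlying `lm` fit.
#' @export
#' @examples
#' x <- seq(0, 1000, 100)
#' fit_trend(x, 2 + 0.01 * x - 1e-5 * x^2, degree = 2)$x_at_extremum  # 500
fit_trend <- function(x, y, kind = c("polynomial", "linear"), degree = 2) {
  kind <- match.arg(kind)
  if (kind == "linear") degree <- 1L
  degree <- as.integer(degree)
  if (degree < 1L) stop_domain("'degree' must be at least 1")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < degree + 2L)
    stop_domain(sprintf(
      "need at least degree + 2 = %d points for a degree-%d regression (got %d)",
      degree + 2L, degree, n))
  if (length(unique(x)) < degree + 1L)
    stop_domain("rank-deficient design: too few distinct x values")

  fit <- stats::lm(y ~ poly(x, degree, raw = TRUE))
  beta <- unname(stats::coef(fit))        # ascending power
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot > 0) 1 - sum(stats::residuals(fit)^2) / sstot else NA_real_

  x_ext <- NA_real_
  if (degree >= 2L) {
    dcoef <- beta[-1L] * seq_len(degree)  # derivative, ascending power
    roots <- polyroot(dcoef)
    real <- Re(roots)[abs(Im(roots)) < 1e-8 * (1 + abs(Re(roots)))]
    real <- real[real >= min(x) & real <= max(x)]
    if (length(real)) {
      # for the unimodal fluxes the relevant extremum is the maximum
      vals <- vapply(real, function(r) sum(beta * r^(0:degree)), 0)
      x_ext <- real[which.max(vals)]
    }
  }

  structure(list(kind = kind, degree = degree, coefficients = beta,
                 r2 = r2, x_at_extremum = x_ext, n = n, lm = fit),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s trend, degree %d (n = %d)\n",
              if (x$kind == "linear") "Linear" else "Polynomial",
              x$degree, x$n))
  cat("Coefficients (ascending power):",
      paste(signif(x$coefficients, digits), collapse = ", "), "\n")
  cat(sprintf("R2 = %.*f", digits, x$r2))
  if (!is.na(x$x_at_extremum))
    cat(sprintf("; extremum at x = %.*f", digits, x$x_at_extremum))
  cat("\n")
  invisible(x)
}

#' @export
predict.trend_fit <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata[[1L]] else newdata
  vapply(x, function(v) sum(object$coefficients * v^(0:object$degree)), 0)
}

#' @export
coef.trend_fit <- function(object, ...) object$coefficients

#' Grid CO2 level of maximal flux, with smoothed counterpart
#'
#' Returns the CO2 level at which the replicate-mean flux peaks (ties break
#' to the lowest level).  When a quadratic trend can be fitted, the smoothed
#' extremum from [fit_trend()] is reported alongside; a monotone series is
#' flagged (the endpoint then stands in for a peak).
#'
#' @param ca CO2 levels.
#' @param y Flux means.
#' @param degree Degree for the smoothing trend (default 2); `NULL` skips it.
#' @return List: `ca_peak`, `smoothed_peak` (NA when unavailable),
#'   `monotone` flag.
#' @export
#' @examples
#' peak_ca(c(0, 200, 600, 1200), c(4.9, 9.1, 12.3, 4.9))$ca_peak
peak_ca <- function(ca, y, degree = 2) {
  if (!length(ca) || length(ca) != length(y))
    stop_domain("'ca' and 'y' must be non-empty and of equal length")
  ord <- order(ca)
  ca <- ca[ord]; y <- y[ord]
  peak <- ca[which(y == max(y))[1L]]
  d <- diff(y)
  monotone <- all(d >= 0) || all(d <= 0)
  smoothed <- NA_real_
  if (!is.null(degree) && length(ca) >= degree + 2 &&
      length(unique(ca)) >= degree + 1) {
    smoothed <- fit_trend(ca, y, "polynomial", degree)$x_at_extremum
  }
  list(ca_peak = peak, smoothed_peak = smoothed, monotone = monotone)
}
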