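# Half-normal detection machinery.
#
# Detection of a group at perpendicular distance y declines as
# g(y) = exp(-y^2 / (2 sigma^2)); the scale sigma is log-linear in binary
# observational covariates (sea conditions), sigma = exp(Y alpha), where Y
# carries an intercept so that the baseline scale is exp(alpha[1]) km.

#' Detection scale from observational covariates
#'
#' @param Y Design matrix (or vector) of observational covariates,
#'   including the leading intercept column.
#' @param alpha Coefficient vector on the log scale, same length as
#'   `ncol(Y)`.
#' @return Detection scale(s) `sigma = exp(Y %*% alpha)` in km.
#' @export
sigma_for <- function(Y, alpha) {
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
  Y <- as.matrix(Y)
  if (!all(is.finite(alpha))) stop_("'alpha' must be finite")
  if (ncol(Y) != length(alpha))
    stop_(sprintf("design has %d columns but 'alpha' has length %d",
                  ncol(Y), length(alpha)))
  as.numeric(exp(Y %*% alpha))
}

#' Mean detection probability over the truncation strip
#'
#' For groups placed uniformly in perpendicular distance on `(0, W)` and
#' detected with half-normal probability `exp(-y^2 / (2 sigma^2))`, the
#' average detection probability is
#' \deqn{p = \frac{1}{W}\int_0^W e^{-y^2/2\sigma^2}\,dy
#'         = \frac{\sigma\sqrt{2\pi}}{W}\left(\Phi(W/\sigma) -
#'           \tfrac12\right),}
#' which is in `(0, 1]` and non-decreasing in `sigma`.
#'
#' @param sigma Detection scale(s), km (> 0).
#' @param W Truncation distance, km (> 0).
#' @return Mean detection probability, vectorized over `sigma`.
#' @export
mean_detection_probability <- function(sigma, W) {
  check_number(W, "W", lower = 0, strict = TRUE)
  if (any(!is.finite(sigma) | sigma <= 0))
    stop_("'sigma' must be positive and finite")
  p <- sigma * sqrt(2 * pi) / W * (stats::pnorm(W / sigma) - 0.5)
  pmin(p, 1)
}

#' Log density of an observed perpendicular distance
#'
#' Conditional on detection, an observed distance on `(0, W)` has density
#' `f(y) = exp(-y^2/(2 sigma^2)) / Z` with normalizer
#' `Z = sigma * sqrt(2*pi) * (pnorm(W/sigma) - 1/2) = W * p`.
#' This un-binned density is the term through which the sighting distances
#' inform the detection coefficients in the joint model.
#'
#' @param y Perpendicular distance(s) in `[0, W]`, km.
#' @param sigma Detection scale(s), km (> 0); recycled against `y`.
#' @param W Truncation distance, km.
#' @return Log density values.
#' @export
distance_log_density <- function(y, sigma, W) {
  check_number(W, "W", lower = 0, strict = TRUE)
  if (any(!is.finite(sigma) | sigma <= 0))
    stop_("'sigma' must be positive and finite")
  if (any(y < 0 | y > W))
    stop_("perpendicular distances must lie in [0, W]")
  log_z <- log(sigma) + 0.5 * log(2 * pi) +
    stats::pnorm(W / sigma, log.p = TRUE) +
    log1p(-0.5 / stats::pnorm(W / sigma))
  -y^2 / (2 * sigma^2) - log_z
}
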