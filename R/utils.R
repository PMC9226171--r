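# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_(sprintf("'%s' must be a single finite number", name))
  ok <- if (strict) (x > lower && x < upper) else (x >= lower && x <= upper)
  if (!ok)
    stop_(sprintf("'%s' = %g is outside %s%g, %g%s", name, x,
                  if (strict) "(" else "[", lower, upper,
                  if (strict) ")" else "]"))
  invisible(x)
}

#' Number of posterior draws retained by an MCMC protocol
#'
#' Bookkeeping for a burn-in + thinning protocol: each chain keeps one of
#' every `thin` post-burn-in iterations, so the total posterior sample is
#' `chains * floor((iter - burnin) / thin)`.
#'
#' @param chains Number of independent chains.
#' @param iter Iterations per chain (including burn-in).
#' @param burnin Iterations discarded from the start of each chain.
#' @param thin Keep one draw in every `thin` retained iterations.
#' @return Integer number of retained posterior draws.
#' @examples
#' mcmc_retained(chains = 3, iter = 70000, burnin = 40000, thin = 50)
#' @export
mcmc_retained <- function(chains, iter, burnin, thin) {
  check_number(chains, "chains", lower = 1)
  check_number(iter, "iter", lower = 1)
  check_number(burnin, "burnin", lower = 0)
  check_number(thin, "thin", lower = 1)
  if (burnin >= iter) stop_("'burnin' must be smaller than 'iter'")
  as.integer(chains) * (as.integer(iter - burnin) %/% as.integer(thin))
}

#' Split-chain potential scale reduction factor
#'
#' Split-\eqn{\widehat{R}}: each chain is split in half and the classical
#' between/within variance ratio is computed over the resulting 2m
#' half-chains, which also flags non-stationarity within a chain.
#'
#' @param x Numeric matrix of draws, one column per chain (equal lengths).
#' @return A single \eqn{\widehat{R}} value (1 indicates convergence).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) return(NA_real_)
  half <- n %/% 2L
  splits <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2L, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Posterior summary row: mean, sd and the standard quantiles.
post_summary <- function(x) {
  q <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
  c(mean = mean(x), sd = stats::sd(x), `2.5%` = q[1], `50%` = q[2],
    `97.5%` = q[3])
}

#' Austral season of a calendar month
#'
#' Southern-hemisphere survey seasons: summer (Jan-Mar), autumn (Apr-Jun),
#' spring (Oct-Dec).  Winter months (Jul-Sep), when no surveys take place,
#' map to `NA`.
#'
#' @param month Integer month(s) in 1..12, or `Date`s.
#' @return Character vector of `"summer"`, `"autumn"`, `"spring"` or `NA`.
#' @export
austral_season <- function(month) {
  if (inherits(month, "Date")) month <- as.integer(format(month, "%m"))
  if (any(!is.na(month) & (month < 1 | month > 12)))
    stop_("'month' must be in 1..12")
  out <- rep(NA_character_, length(month))
  out[month %in% 1:3] <- "summer"
  out[month %in% 4:6] <- "autumn"
  out[month %in% 10:12] <- "spring"
  out
}
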