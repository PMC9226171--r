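# Fit-assessment battery: simulation-based scaled residuals with
# dispersion / outlier / uniformity / zero-percentage tests, a
# posterior-predictive chi-squared check (Bayesian p-value and c-hat),
# and Moran's I residual spatial autocorrelation.

# Evenly spaced draw indices, so replicates span all chains.
spread_draws <- function(n_total, n_rep) {
  unique(round(seq(1, n_total, length.out = n_rep)))
}

#' Replicate observed counts from the fitted generative model
#'
#' For each selected posterior draw, counts are re-simulated from the
#' fitted chain zero-inflation -> Poisson -> binomial thinning at that
#' draw's parameters.  `"conditional"` replication keeps the draw's own
#' segment random effects (the usual residual convention for
#' observation-level effects); `"marginal"` redraws them from
#' `Normal(0, sigma_tau)`.
#'
#' @param fit A [fit_bnmm()] result.
#' @param n_rep Number of replicate data sets (at most the number of
#'   retained draws).
#' @param condition `"conditional"` (default) or `"marginal"`.
#' @param seed Optional seed.
#' @return Integer matrix, segments x replicates, with attributes
#'   `draw_ids` and `expected` (the matrix of per-draw expected counts
#'   `psi * lambda_i * p_i`).
#' @export
posterior_replicates <- function(fit, n_rep = 250,
                                 condition = c("conditional", "marginal"),
                                 seed = NULL) {
  stopifnot(inherits(fit, "bnmm_fit"))
  condition <- match.arg(condition)
  if (n_rep > nrow(fit$draws))
    stop_("n_rep exceeds the number of posterior draws")
  if (!is.null(seed)) set.seed(seed)
  ids <- spread_draws(nrow(fit$draws), n_rep)
  md <- fit$data
  reps <- matrix(NA_integer_, md$n_seg, length(ids))
  expected <- matrix(NA_real_, md$n_seg, length(ids))
  for (r in seq_along(ids)) {
    pars <- draw_params(fit, ids[r])
    lambda <- pars$lambda
    if (condition == "marginal" && fit$re_tau)
      lambda <- lambda * exp(-pars$tau +
                               stats::rnorm(md$n_seg, 0, pars$sigma_tau))
    occ <- stats::runif(md$n_seg) < pars$psi
    N <- ifelse(occ, stats::rpois(md$n_seg, lambda), 0L)
    reps[, r] <- stats::rbinom(md$n_seg, N, pars$p_i)
    expected[, r] <- pars$psi * lambda * pars$p_i
  }
  attr(reps, "draw_ids") <- ids
  attr(reps, "expected") <- expected
  reps
}

#' Simulation-based scaled (PIT) residuals
#'
#' Randomized probability-integral-transform residual of each observation
#' within its replicate distribution:
#' `(#\{rep < obs\} + U (#\{rep = obs\} + 1)) / (n_rep + 1)` with
#' `U ~ Uniform(0,1)` breaking ties.  Under a correctly specified model
#' the residuals are i.i.d. `Uniform(0, 1)`.
#'
#' @param observed Integer vector of observed counts.
#' @param replicates Matrix from [posterior_replicates()] (observations in
#'   rows).
#' @param seed Optional seed for the tie-breaking jitter.
#' @return Numeric residuals in `[0, 1]`, one per observation.
#' @export
scaled_residuals <- function(observed, replicates, seed = NULL) {
  replicates <- as.matrix(replicates)
  if (length(observed) != nrow(replicates))
    stop_("'observed' must match rows of 'replicates'")
  n_rep <- ncol(replicates)
  if (n_rep < 50)
    warning("fewer than 50 replicates; scaled residuals will be coarse")
  if (!is.null(seed)) set.seed(seed)
  below <- rowSums(replicates < observed)
  ties <- rowSums(replicates == observed)
  (below + stats::runif(length(observed)) * (ties + 1)) / (n_rep + 1)
}

# Two-sided Monte-Carlo p-value for an observed statistic against its
# replicate distribution (ties count toward both tails).
mc_two_sided <- function(stat_obs, stat_rep) {
  R <- length(stat_rep)
  p_ge <- (1 + sum(stat_rep >= stat_obs)) / (R + 1)
  p_le <- (1 + sum(stat_rep <= stat_obs)) / (R + 1)
  min(1, 2 * min(p_ge, p_le))
}

#' Residual test battery
#'
#' Quantile-free summary tests on the replicate distribution:
#' \itemize{
#' \item dispersion: ratio of the observed count variance to the mean
#'   replicate variance, with a two-sided Monte-Carlo p-value;
#' \item outliers: residuals outside `(1/(R+1), R/(R+1))` against their
#'   binomial expectation;
#' \item uniformity: Kolmogorov-Smirnov distance of the residuals from
#'   `Uniform(0, 1)`;
#' \item zero inflation: observed percentage of zeros against its
#'   replicate distribution.
#' }
#'
#' @param residuals From [scaled_residuals()].
#' @param observed Observed counts.
#' @param replicates Matrix from [posterior_replicates()].
#' @return List with elements `dispersion_ratio, dispersion_p,
#'   outlier_count, outlier_expected, outlier_p, ks_statistic, ks_p,
#'   pct_zeros_observed, pct_zeros_simulated` (vector), `pct_zeros_p`.
#' @export
residual_tests <- function(residuals, observed, replicates) {
  replicates <- as.matrix(replicates)
  R <- ncol(replicates)
  var_rep <- apply(replicates, 2L, stats::var)
  dispersion_ratio <- stats::var(observed) / mean(var_rep)
  dispersion_p <- mc_two_sided(stats::var(observed), var_rep)
  lo <- 1 / (R + 1); hi <- R / (R + 1)
  n_out <- sum(residuals < lo | residuals > hi)
  p_out_expect <- 2 / (R + 1)
  outlier_p <- stats::binom.test(n_out, length(residuals),
                                 p = p_out_expect)$p.value
  ks <- suppressWarnings(stats::ks.test(residuals, "punif"))
  pct_zero_rep <- 100 * colMeans(replicates == 0)
  pct_zero_obs <- 100 * mean(observed == 0)
  list(dispersion_ratio = dispersion_ratio, dispersion_p = dispersion_p,
       outlier_count = n_out,
       outlier_expected = p_out_expect * length(residuals),
       outlier_p = outlier_p,
       ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
       pct_zeros_observed = pct_zero_obs,
       pct_zeros_simulated = pct_zero_rep,
       pct_zeros_p = mc_two_sided(pct_zero_obs, pct_zero_rep))
}

#' Posterior-predictive chi-squared check
#'
#' For each selected draw the Pearson discrepancy
#' `D = sum_i (n_i - e_i)^2 / (e_i + eps)` is computed for the observed
#' counts (`D_obs`) and for counts replicated at the same draw (`D_rep`),
#' with `e_i = psi * lambda_i * p_i` the expected count.  The Bayesian
#' p-value is `Pr(D_rep >= D_obs)` (ties count as >=) and c-hat is
#' `sum(D_obs) / sum(D_rep)`; a well-fitting model gives a p-value away
#' from 0 and 1 and c-hat near 1.
#'
#' @param fit A [fit_bnmm()] result.
#' @param n_draws Number of posterior draws to use.
#' @param eps Floor added to expected counts (default 1e-6).
#' @param condition Replication mode, as in [posterior_replicates()].
#' @param seed Optional seed.
#' @return List: `bayes_p`, `c_hat`, `D_obs`, `D_rep`.
#' @export
posterior_predictive_chisq <- function(fit, n_draws = min(500,
                                                          nrow(fit$draws)),
                                       eps = 1e-6,
                                       condition = "conditional",
                                       seed = NULL) {
  reps <- posterior_replicates(fit, n_draws, condition = condition,
                               seed = seed)
  expected <- attr(reps, "expected")
  n <- fit$data$n
  D_obs <- colSums((n - expected)^2 / (expected + eps))
  D_rep <- colSums((reps - expected)^2 / (expected + eps))
  list(bayes_p = mean(D_rep >= D_obs),
       c_hat = sum(D_obs) / sum(D_rep),
       D_obs = D_obs, D_rep = D_rep)
}

#' Moran's I residual spatial autocorrelation
#'
#' `I = (n / sum(w)) * sum_ij w_ij (r_i - rbar)(r_j - rbar) /
#' sum_i (r_i - rbar)^2` with inverse-Euclidean-distance weights
#' (`w_ii = 0`) by default, or binary k-nearest-neighbour weights.  The
#' p-value comes from random permutations of the residuals over the
#' coordinates (two-sided on the statistic).  Under the null,
#' `E[I] = -1/(n-1)`.
#'
#' @param residuals Numeric residuals (>= 10 values).
#' @param coords Two-column matrix/data frame of planar coordinates.
#' @param weights `"invdist"` (default) or `"knn"`.
#' @param k Neighbours for `"knn"` weights.
#' @param n_perm Number of permutations (>= 999 recommended).
#' @param max_weight Cap applied to inverse-distance weights; defaults to
#'   the largest finite weight, which handles coincident points.
#' @param seed Optional seed.
#' @return List: `statistic`, `expectation`, `p_value`, `n_perm`.
#' @export
morans_i <- function(residuals, coords, weights = c("invdist", "knn"),
                     k = 4, n_perm = 999, max_weight = NULL,
                     seed = NULL) {
  weights <- match.arg(weights)
  coords <- as.matrix(coords)
  n <- length(residuals)
  if (n < 10L) stop_("need at least 10 residuals for Moran's I")
  if (nrow(coords) != n) stop_("'coords' must match 'residuals'")
  if (!is.null(seed)) set.seed(seed)
  d <- as.matrix(stats::dist(coords))
  if (weights == "invdist") {
    wmat <- 1 / d
    diag(wmat) <- 0
    finite_max <- max(wmat[is.finite(wmat)])
    cap <- max_weight %||% finite_max
    wmat[!is.finite(wmat)] <- cap
    wmat[wmat > cap] <- cap
    diag(wmat) <- 0
  } else {
    wmat <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(d[i, ])[2:(k + 1)]
      wmat[i, nb] <- 1
    }
  }
  stat <- function(r) {
    rc <- r - mean(r)
    n / sum(wmat) * sum(wmat * outer(rc, rc)) / sum(rc^2)
  }
  I_obs <- stat(residuals)
  I_perm <- vapply(seq_len(n_perm),
                   function(i) stat(sample(residuals)), numeric(1))
  list(statistic = I_obs, expectation = -1 / (n - 1),
       p_value = mc_two_sided(I_obs, I_perm), n_perm = n_perm)
}

#' Full model-checking report
#'
#' Runs the whole battery against a fitted model: posterior replication,
#' scaled residuals, the residual test suite, the posterior-predictive
#' chi-squared check, and (when segment midpoints are available) Moran's
#' I on the residuals.
#'
#' @param fit A [fit_bnmm()] result.
#' @param n_rep Replicate data sets for the residual battery.
#' @param n_perm Permutations for Moran's I.
#' @param seed Seed for all replication randomness.
#' @return Object of class `bnmm_checks`: all [residual_tests()] fields
#'   plus `bayes_p`, `c_hat`, `morans_i`, `morans_p`, and `residuals`.
#' @export
check_model <- function(fit, n_rep = 250, n_perm = 999, seed = 1) {
  stopifnot(inherits(fit, "bnmm_fit"))
  set.seed(seed)
  reps <- posterior_replicates(fit, min(n_rep, nrow(fit$draws)))
  res <- scaled_residuals(fit$data$n, reps)
  tests <- residual_tests(res, fit$data$n, reps)
  ppc <- posterior_predictive_chisq(fit)
  seg <- fit$data$segments
  mor <- if (all(c("x_mid", "y_mid") %in% names(seg)) &&
             fit$data$n_seg >= 10)
    morans_i(res, seg[, c("x_mid", "y_mid")], n_perm = n_perm)
  else NULL
  structure(c(tests,
              list(bayes_p = ppc$bayes_p, c_hat = ppc$c_hat,
                   morans_i = mor$statistic %||% NA_real_,
                   morans_p = mor$p_value %||% NA_real_,
                   residuals = res, n_rep = ncol(reps))),
            class = "bnmm_checks")
}

#' @export
print.bnmm_checks <- function(x, ...) {
  cat("Model checks (", x$n_rep, " posterior replicates)\n", sep = "")
  cat(sprintf("  dispersion ratio %.3f (p = %.3f)\n",
              x$dispersion_ratio, x$dispersion_p))
  cat(sprintf("  outliers %d (expected %.1f, p = %.3f)\n",
              x$outlier_count, x$outlier_expected, x$outlier_p))
  cat(sprintf("  KS uniformity %.3f (p = %.3f)\n",
              x$ks_statistic, x$ks_p))
  cat(sprintf("  %% zeros observed %.1f vs simulated %.1f (p = %.3f)\n",
              x$pct_zeros_observed, mean(x$pct_zeros_simulated),
              x$pct_zeros_p))
  cat(sprintf("  Bayesian p = %.3f, c-hat = %.3f\n", x$bayes_p, x$c_hat))
  if (!is.na(x$morans_i))
    cat(sprintf("  Moran's I = %.4f (p = %.3f)\n", x$morans_i,
                x$morans_p))
  invisible(x)
}
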