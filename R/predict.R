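# Project the fitted model onto a prediction grid and summarize
# abundance.

#' Per-draw predicted group density on a grid
#'
#' `N_g = psi * exp(beta0 + X_g beta)` groups/km2 for every retained
#' draw: the unconditional expectation of the zero-inflated Poisson,
#' excluding the observation-level random effect (which absorbs
#' segment-level sampling noise, not habitat signal).  Grid covariates
#' must be standardized with the training centring/scaling constants,
#' never re-estimated on the grid.
#'
#' @param fit A [fit_bnmm()] result.
#' @param grid A [cov_grid] or data frame holding every model covariate.
#' @param standardization Optional list with `center` and `scale` (from
#'   [standardize_covariates()] on the training table) applied to the
#'   grid covariates; omit if the grid is already on the training scale.
#' @param include_psi Multiply by the occupancy probability (default
#'   `TRUE`, the unconditional expectation); `FALSE` gives the
#'   positive-component density.
#' @param tau_correction Apply the lognormal random-effect correction
#'   `exp(sigma_tau^2 / 2)` (default `FALSE`).
#' @return Matrix, draws x cells, in groups/km2, with attribute
#'   `extrapolated`: cells whose standardized covariates fall outside the
#'   training range.
#' @export
predict_group_density <- function(fit, grid, standardization = NULL,
                                  include_psi = TRUE,
                                  tau_correction = FALSE) {
  stopifnot(inherits(fit, "bnmm_fit"))
  covs <- fit$covariates
  Xg <- if (inherits(grid, "cov_grid")) grid$covariates else as.matrix(grid)
  miss <- setdiff(covs, colnames(Xg))
  if (length(miss))
    stop_("prediction grid lacks covariate(s): ",
          paste(miss, collapse = ", "))
  Xg <- Xg[, covs, drop = FALSE]
  if (!is.null(standardization))
    Xg <- sweep(sweep(Xg, 2L, standardization$center[covs]), 2L,
                standardization$scale[covs], "/")
  if (any(!is.finite(Xg))) stop_("non-finite grid covariate values")
  extra <- rep(FALSE, nrow(Xg))
  for (j in seq_along(covs)) {
    rng <- range(fit$data$X[, covs[j]])
    extra <- extra | Xg[, j] < rng[1] | Xg[, j] > rng[2]
  }
  beta0 <- fit$draws[, "beta0"]
  B <- if (length(covs))
    fit$draws[, paste0("beta_", covs), drop = FALSE]
  else matrix(0, nrow(fit$draws), 0)
  eta <- matrix(beta0, nrow(fit$draws), nrow(Xg)) +
    (if (length(covs)) B %*% t(Xg) else 0)
  dens <- exp(eta)
  if (include_psi && fit$zero_inflation)
    dens <- dens * fit$draws[, "psi"]
  if (tau_correction && fit$re_tau)
    dens <- dens * exp(fit$draws[, "sigma_tau"]^2 / 2)
  attr(dens, "extrapolated") <- extra
  dens
}

#' Abundance posterior from a predicted density surface
#'
#' Per draw, total individuals
#' `sum_g N_g * area_g * mean_group_size`, combining the density draws
#' with group-size posterior draws aligned one-to-one so both
#' uncertainties propagate.
#'
#' @param density Draws-by-cells matrix from [predict_group_density()].
#' @param areas Cell areas, km2 (scalar or per cell).
#' @param group_size A [group_size_summary()] result, a numeric vector of
#'   mean-size draws (length matching the density draws), or a single
#'   fixed mean size.
#' @param season Optional season label.
#' @return Object of class `abundance_summary`: `draws` (total
#'   individuals per draw), `mean, sd, q2.5, median, q97.5`, `season`.
#' @export
abundance <- function(density, areas, group_size = 1, season = NA) {
  density <- as.matrix(density)
  if (length(areas) == 1L) areas <- rep(areas, ncol(density))
  if (length(areas) != ncol(density))
    stop_("'areas' must have one value per grid cell")
  if (any(areas <= 0)) stop_("cell areas must be positive")
  sizes <- if (inherits(group_size, "group_size_post"))
    group_size$draws[, "mean"] else group_size
  if (length(sizes) == 1L) sizes <- rep(sizes, nrow(density))
  if (length(sizes) != nrow(density))
    stop_("group-size draws are not aligned with density draws (",
          length(sizes), " vs ", nrow(density), ")")
  totals <- drop(density %*% areas) * sizes
  s <- post_summary(totals)
  structure(list(draws = totals, mean = s[["mean"]], sd = s[["sd"]],
                 q2.5 = s[["2.5%"]], median = s[["50%"]],
                 q97.5 = s[["97.5%"]], season = season),
            class = "abundance_summary")
}

#' @export
print.abundance_summary <- function(x, ...) {
  cat(sprintf(paste0("Abundance posterior%s: mean %.1f, sd %.1f, ",
                     "2.5%% %.1f, median %.1f, 97.5%% %.1f\n"),
              if (is.na(x$season)) "" else paste0(" (", x$season, ")"),
              x$mean, x$sd, x$q2.5, x$median, x$q97.5))
  invisible(x)
}

#' Pool seasonal abundance posteriors
#'
#' Seasonal posteriors are concatenated with equal weight and
#' re-summarized, expressing uncertainty about which seasonal
#' environmental conditions are the appropriate ones.
#'
#' @param ... `abundance_summary` objects (or a single list of them).
#' @return A pooled `abundance_summary` with season `"pooled"`.
#' @export
pool_seasonal <- function(...) {
  seasons <- list(...)
  if (length(seasons) == 1L && !inherits(seasons[[1]], "abundance_summary"))
    seasons <- seasons[[1]]
  if (!length(seasons)) stop_("no seasonal posteriors supplied")
  ok <- vapply(seasons, inherits, logical(1), "abundance_summary")
  if (!all(ok)) stop_("all inputs must be abundance_summary objects")
  draws <- unlist(lapply(seasons, `[[`, "draws"), use.names = FALSE)
  s <- post_summary(draws)
  structure(list(draws = draws, mean = s[["mean"]], sd = s[["sd"]],
                 q2.5 = s[["2.5%"]], median = s[["50%"]],
                 q97.5 = s[["97.5%"]], season = "pooled"),
            class = "abundance_summary")
}
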