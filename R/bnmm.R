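# Single-step hierarchical count model.
#
# Latent group counts per effort segment follow a zero-inflated Poisson
# with an effort-area offset and an observation-level normal random
# effect on the log mean:
#   N_i = 0                     with probability 1 - psi
#   N_i ~ Poisson(lambda_i)     otherwise,
#   lambda_i = 2 W L_i exp(beta0 + X_i beta + tau_i).
# Observed counts are binomially thinned, n_i ~ Binomial(N_i, p_i), with
# p_i the mean half-normal detection probability over the truncation
# strip at the segment's sea conditions.  The likelihood is evaluated
# with N_i marginalized analytically: a binomially thinned Poisson is
# Poisson with mean lambda_i p_i, so
#   n_i = 0 contributes log[(1 - psi) + psi exp(-lambda_i p_i)]
#   n_i > 0 contributes log psi + Poisson(n_i; lambda_i p_i),
# and the un-binned perpendicular distances contribute their conditional
# half-normal density, tying the detection coefficients to the counts in
# one step so that all uncertainty propagates jointly.

DET_COLS <- c("wave_bin", "wind_bin", "sea_bin")

# Pre-digest the analysis table into the structures the likelihood needs.
# Detection covariates are binary, so segments collapse into at most 8
# distinct detection classes; distance terms reduce to per-class
# sufficient statistics (count, sum of squared distances).
build_model_data <- function(segments, sightings, W, covariates) {
  check_number(W, "W", lower = 0, strict = TRUE)
  need <- c("segment_id", "length_km", "n", DET_COLS, covariates)
  miss <- setdiff(need, names(segments))
  if (length(miss))
    stop_("segments table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(segments$n < 0)) stop_("negative observed count n_i")
  if (any(segments$length_km <= 0)) stop_("segment lengths must be > 0")
  unknown <- !(sightings$segment_id %in% segments$segment_id)
  if (any(unknown))
    stop_("sighting(s) reference unknown segment(s): ",
          paste(unique(sightings$segment_id[unknown]), collapse = ", "))
  tab <- tabulate(match(sightings$segment_id, segments$segment_id),
                  nbins = nrow(segments))
  if (!all(tab == segments$n))
    stop_("segment counts n_i are inconsistent with the sightings table")
  if (any(sightings$perp_dist_km < 0 | sightings$perp_dist_km > W))
    stop_("perpendicular distances must lie in [0, W]")
  X <- as.matrix(segments[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  Ydet <- cbind(intercept = 1,
                as.matrix(segments[, DET_COLS, drop = FALSE]))
  key <- interaction(segments$wave_bin, segments$wind_bin,
                     segments$sea_bin, drop = TRUE)
  class_id <- as.integer(key)
  Yu <- Ydet[!duplicated(class_id), , drop = FALSE]
  Yu <- Yu[order(unique(class_id)), , drop = FALSE]
  sgt_class <- class_id[match(sightings$segment_id, segments$segment_id)]
  nclass <- nrow(Yu)
  m_c <- tabulate(sgt_class, nbins = nclass)
  sy2_c <- vapply(seq_len(nclass), function(cc)
    sum(sightings$perp_dist_km[sgt_class == cc]^2), numeric(1))
  list(n = as.integer(segments$n), L = segments$length_km,
       A = 2 * W * segments$length_km, X = X, W = W,
       covariates = covariates, Ydet = Ydet, Yu = Yu,
       class_id = class_id, m_c = m_c, sy2_c = sy2_c,
       y = sightings$perp_dist_km, sgt_class = sgt_class,
       n_seg = nrow(segments), segments = segments,
       sightings = sightings)
}

# Count-part log likelihood per segment for mean vector mu (already
# thinned), under the ZIP mixture with occupancy psi.
zip_count_ll <- function(n, mu, psi) {
  out <- numeric(length(n))
  z <- n == 0L
  out[z] <- if (psi == 1) -mu[z] else log((1 - psi) + psi * exp(-mu[z]))
  if (any(!z))
    out[!z] <- log(psi) + stats::dpois(n[!z], mu[!z], log = TRUE)
  out
}

# Full joint log likelihood given a digested model-data list.
ll_internal <- function(md, beta0, beta, psi, alpha, tau, sigma_tau,
                        include_tau_prior = TRUE, p_fixed = NULL) {
  if (is.null(p_fixed)) {
    sigma_c <- as.numeric(exp(md$Yu %*% alpha))
    p_c <- mean_detection_probability(sigma_c, md$W)
    log_z_c <- log(sigma_c) + 0.5 * log(2 * pi) +
      log(stats::pnorm(md$W / sigma_c) - 0.5)
    dist_ll <- sum(-md$sy2_c / (2 * sigma_c^2) - md$m_c * log_z_c)
    p_i <- p_c[md$class_id]
  } else {
    dist_ll <- 0
    p_i <- p_fixed
  }
  eta <- beta0 + if (length(beta)) drop(md$X %*% beta) else 0
  mu <- md$A * exp(eta + tau) * p_i
  count_ll <- sum(zip_count_ll(md$n, mu, psi))
  tau_ll <- if (include_tau_prior && sigma_tau > 0)
    sum(stats::dnorm(tau, 0, sigma_tau, log = TRUE)) else 0
  count_ll + dist_ll + tau_ll
}

#' Joint log likelihood of the hierarchical count model
#'
#' Evaluates the marginalized zero-inflated-Poisson-binomial likelihood of
#' the observed counts (latent counts integrated out analytically via the
#' thinned-Poisson identity), plus the conditional half-normal density of
#' all observed perpendicular distances, plus the normal density of the
#' segment random effects when present.
#'
#' @param params List with `beta0`, `beta` (environmental coefficients,
#'   may be length 0), `psi`, `alpha` (detection coefficients incl.
#'   intercept), `sigma_tau`, and optionally `tau` (per-segment effects;
#'   defaults to zeros).
#' @param segments Analysis table: `segment_id, length_km, n`, the binary
#'   condition flags `wave_bin, wind_bin, sea_bin`, and the covariate
#'   columns named in `covariates`.
#' @param sightings Data frame `segment_id, perp_dist_km`; must tabulate
#'   exactly to `segments$n`.
#' @param W Truncation distance, km.
#' @param covariates Names of the environmental covariate columns.
#' @param include_tau_prior Include the `Normal(0, sigma_tau^2)` density
#'   of `tau` (default `TRUE`).
#' @return Scalar log likelihood.
#' @export
joint_log_likelihood <- function(params, segments, sightings, W,
                                 covariates = character(),
                                 include_tau_prior = TRUE) {
  md <- build_model_data(segments, sightings, W, covariates)
  tau <- params$tau %||% numeric(md$n_seg)
  check_number(params$psi, "psi", lower = 0, upper = 1)
  ll_internal(md, params$beta0, params$beta, params$psi, params$alpha,
              tau, params$sigma_tau %||% 0,
              include_tau_prior = include_tau_prior)
}

#' Prior specification for the hierarchical count model
#'
#' Vague-by-default priors on the sampling scale: independent
#' `Normal(0, sd)` on the log-linear coefficients, `Uniform(0, 1)` on the
#' occupancy probability, and half-normal on the random-effect SD.
#'
#' @param beta_sd,alpha_sd Prior SD of the count and detection
#'   coefficients.
#' @param sigma_tau_sd Scale of the half-normal prior on `sigma_tau`.
#' @return List of prior hyperparameters.
#' @export
bnmm_priors <- function(beta_sd = 10, alpha_sd = 10, sigma_tau_sd = 2) {
  list(beta_sd = beta_sd, alpha_sd = alpha_sd, sigma_tau_sd = sigma_tau_sd)
}

# Log prior of the top-level parameter vector on the sampling scale
# (logit psi, log sigma_tau), Jacobians included.
log_prior <- function(beta0, beta, lpsi, alpha, lst, priors,
                      zero_inflation, re_tau, p_fixed) {
  lp <- stats::dnorm(beta0, 0, priors$beta_sd, log = TRUE) +
    sum(stats::dnorm(beta, 0, priors$beta_sd, log = TRUE))
  if (is.null(p_fixed))
    lp <- lp + sum(stats::dnorm(alpha, 0, priors$alpha_sd, log = TRUE))
  if (zero_inflation) {
    psi <- stats::plogis(lpsi)
    lp <- lp + log(psi) + log1p(-psi)      # U(0,1) through the logit map
  }
  if (re_tau) {
    st <- exp(lst)
    lp <- lp + stats::dnorm(st, 0, priors$sigma_tau_sd, log = TRUE) +
      log(2) + lst                          # half-normal + Jacobian
  }
  lp
}

#' Fit the hierarchical count model by adaptive MCMC
#'
#' Adaptive component-wise random-walk Metropolis on the marginalized
#' likelihood: proposal scales for the top-level parameters follow a
#' diminishing Robbins-Monro adaptation toward 44% acceptance during
#' burn-in, and the per-segment random effects are updated jointly with
#' vectorized independent Metropolis steps (they are conditionally
#' independent given the top level).  Latent counts are never sampled;
#' [latent_counts()] reconstructs them exactly from their conditional
#' distribution when needed.
#'
#' @param segments,sightings,W,covariates As in
#'   [joint_log_likelihood()].
#' @param chains,iter,burnin,thin MCMC protocol; the retained sample size
#'   is `mcmc_retained(chains, iter, burnin, thin)`.
#' @param seed Integer seed (chain c uses `seed + c`).
#' @param re_tau Include the observation-level random effect (default
#'   `TRUE`).
#' @param zero_inflation Include the zero-inflation component (default
#'   `TRUE`); if `FALSE`, `psi` is fixed at 1.
#' @param p_fixed Optionally fix the detection probability (e.g. 1) and
#'   drop the detection sub-model; used for degenerate checks.
#' @param priors A [bnmm_priors()] list.
#' @param save_tau Keep per-draw random effects (needed for conditional
#'   posterior replication; default `TRUE`).
#' @return An object of class `bnmm_fit`: `draws` (matrix, one row per
#'   retained draw), `tau` (draws x segments, or `NULL`), `chain`,
#'   `rhat`, `converged`, `accept`, the digested data, and the protocol.
#'   A warning is issued (and `converged` set `FALSE`) if any split-R-hat
#'   is 1.1 or more.
#' @export
fit_bnmm <- function(segments, sightings, W, covariates = character(),
                     chains = 3, iter = 6000, burnin = iter %/% 2,
                     thin = 2, seed = 1, re_tau = TRUE,
                     zero_inflation = TRUE, p_fixed = NULL,
                     priors = bnmm_priors(), save_tau = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  md <- build_model_data(segments, sightings, W, covariates)
  if (sum(md$n) == 0L)
    warning("no segment has a positive count; the intercept posterior ",
            "follows the prior")
  keep_per_chain <- mcmc_retained(1, iter, burnin, thin)
  k <- length(covariates)
  par_names <- c("beta0",
                 if (k) paste0("beta_", covariates),
                 if (zero_inflation) "psi",
                 if (is.null(p_fixed))
                   paste0("alpha_", colnames(md$Yu)),
                 if (re_tau) "sigma_tau")

  run_chain <- function(chain_id) {
    set.seed(seed + chain_id)
    # moment-based starting values, jittered per chain
    p_guess <- if (is.null(p_fixed)) 0.5 else p_fixed
    beta0 <- log((sum(md$n) + 0.5) / (sum(md$A) * p_guess * 0.8)) +
      stats::rnorm(1, 0, 0.2)
    beta <- stats::rnorm(k, 0, 0.1)
    lpsi <- stats::qlogis(0.8) + stats::rnorm(1, 0, 0.2)
    sig0 <- if (length(md$y)) max(sqrt(mean(md$y^2)), 0.1 * md$W)
            else md$W / 2
    alpha <- c(log(sig0), numeric(ncol(md$Yu) - 1L)) +
      stats::rnorm(ncol(md$Yu), 0, 0.1)
    lst <- log(0.3) + stats::rnorm(1, 0, 0.2)
    tau <- numeric(md$n_seg)

    th <- c(beta0, beta, if (zero_inflation) lpsi,
            if (is.null(p_fixed)) alpha, if (re_tau) lst)
    npar <- length(th)
    i_b0 <- 1L
    i_beta <- if (k) 1L + seq_len(k) else integer(0)
    i_psi <- if (zero_inflation) 1L + k + 1L else integer(0)
    i_alpha <- if (is.null(p_fixed))
      1L + k + length(i_psi) + seq_len(ncol(md$Yu)) else integer(0)
    i_lst <- if (re_tau) npar else integer(0)

    unpack <- function(th) list(
      beta0 = th[i_b0],
      beta = th[i_beta],
      psi = if (zero_inflation) stats::plogis(th[i_psi]) else 1,
      alpha = if (is.null(p_fixed)) th[i_alpha] else NULL,
      lst = if (re_tau) th[i_lst] else -Inf,
      sigma_tau = if (re_tau) exp(th[i_lst]) else 0)

    lpost <- function(th, tau) {
      pp <- unpack(th)
      lp <- ll_internal(md, pp$beta0, pp$beta, pp$psi, pp$alpha, tau,
                        pp$sigma_tau, include_tau_prior = re_tau,
                        p_fixed = p_fixed) +
        log_prior(pp$beta0, pp$beta,
                  if (zero_inflation) th[i_psi] else 0, pp$alpha,
                  if (re_tau) th[i_lst] else 0, priors,
                  zero_inflation, re_tau, p_fixed)
      if (is.nan(lp)) -Inf else lp    # degenerate corners (sigma -> 0)
    }

    # per-segment count term + tau prior, for the vectorized tau update
    tau_terms <- function(th, tau) {
      pp <- unpack(th)
      p_i <- if (is.null(p_fixed)) {
        sigma_c <- as.numeric(exp(md$Yu %*% pp$alpha))
        mean_detection_probability(sigma_c, md$W)[md$class_id]
      } else p_fixed
      eta <- pp$beta0 + if (k) drop(md$X %*% pp$beta) else 0
      mu <- md$A * exp(eta + tau) * p_i
      zip_count_ll(md$n, mu, pp$psi) +
        stats::dnorm(tau, 0, pp$sigma_tau, log = TRUE)
    }

    log_sd <- rep(log(0.1), npar)
    log_sd_tau <- log(0.5)
    acc <- numeric(npar); acc_tau <- 0; n_tau_up <- 0
    cur_lp <- lpost(th, tau)
    draws <- matrix(NA_real_, keep_per_chain, length(par_names),
                    dimnames = list(NULL, par_names))
    tau_draws <- if (save_tau && re_tau)
      matrix(NA_real_, keep_per_chain, md$n_seg) else NULL
    kept <- 0L
    for (t in seq_len(iter)) {
      gam <- if (t <= burnin) min(0.25, 3 / sqrt(t)) else 0
      for (j in seq_len(npar)) {
        prop <- th
        prop[j] <- th[j] + exp(log_sd[j]) * stats::rnorm(1)
        lp_new <- lpost(prop, tau)
        a <- if (lp_new == -Inf) 0 else exp(min(0, lp_new - cur_lp))
        if (stats::runif(1) < a) {
          th <- prop; cur_lp <- lp_new; acc[j] <- acc[j] + 1
        }
        log_sd[j] <- log_sd[j] + gam * (a - 0.44)
      }
      if (re_tau) {
        cur_terms <- tau_terms(th, tau)
        prop_tau <- tau + exp(log_sd_tau) * stats::rnorm(md$n_seg)
        new_terms <- tau_terms(th, prop_tau)
        new_terms[is.nan(new_terms)] <- -Inf
        a_vec <- ifelse(new_terms == -Inf, 0,
                        exp(pmin(0, new_terms - cur_terms)))
        take <- stats::runif(md$n_seg) < a_vec
        if (any(take)) {
          tau[take] <- prop_tau[take]
          cur_lp <- lpost(th, tau)
        }
        log_sd_tau <- log_sd_tau + gam * (mean(a_vec) - 0.44)
        acc_tau <- acc_tau + mean(take); n_tau_up <- n_tau_up + 1
      }
      if (t > burnin && (t - burnin) %% thin == 0L) {
        kept <- kept + 1L
        pp <- unpack(th)
        draws[kept, ] <- c(pp$beta0, pp$beta,
                           if (zero_inflation) pp$psi,
                           if (is.null(p_fixed)) pp$alpha,
                           if (re_tau) pp$sigma_tau)
        if (!is.null(tau_draws)) tau_draws[kept, ] <- tau
      }
    }
    list(draws = draws, tau = tau_draws,
         accept = c(acc / iter, tau = if (re_tau) acc_tau / n_tau_up))
  }

  res <- lapply(seq_len(chains), run_chain)
  draws <- do.call(rbind, lapply(res, `[[`, "draws"))
  tau <- if (save_tau && re_tau)
    do.call(rbind, lapply(res, `[[`, "tau")) else NULL
  chain <- rep(seq_len(chains), each = keep_per_chain)
  rhat <- vapply(seq_along(par_names), function(j)
    split_rhat(matrix(draws[, j], ncol = chains)), numeric(1))
  names(rhat) <- par_names
  converged <- all(rhat < 1.1, na.rm = TRUE)
  if (!converged)
    warning("MCMC convergence suspect: max split-R-hat = ",
            round(max(rhat, na.rm = TRUE), 3))
  structure(list(
    draws = draws, tau = tau, chain = chain,
    iteration = rep(seq_len(keep_per_chain), chains),
    rhat = rhat, converged = converged,
    accept = lapply(res, `[[`, "accept"),
    data = md, covariates = covariates, W = W,
    re_tau = re_tau, zero_inflation = zero_inflation, p_fixed = p_fixed,
    protocol = list(chains = chains, iter = iter, burnin = burnin,
                    thin = thin, seed = seed,
                    retained = chains * keep_per_chain),
    priors = priors,
    runtime_s = proc.time()[["elapsed"]] - t0
  ), class = "bnmm_fit")
}

#' @export
print.bnmm_fit <- function(x, ...) {
  cat(sprintf(paste0("Hierarchical N-mixture fit: %d segments, %d ",
                     "sightings, W = %g km\n"),
              x$data$n_seg, length(x$data$y), x$W))
  cat(sprintf("%d chains x %d iter (burn-in %d, thin %d): %d draws; max R-hat %.3f\n",
              x$protocol$chains, x$protocol$iter, x$protocol$burnin,
              x$protocol$thin, x$protocol$retained,
              max(x$rhat, na.rm = TRUE)))
  print(summary(x), digits = 3)
  invisible(x)
}

#' @export
summary.bnmm_fit <- function(object, ...) {
  out <- t(apply(object$draws, 2L, post_summary))
  cbind(as.data.frame(out), rhat = object$rhat)
}

#' Reconstruct latent group counts from the fitted posterior
#'
#' The marginalized sampler never stores `N_i`; this draws them exactly
#' from their conditional distribution given each retained draw: for
#' `n_i > 0`, `N_i = n_i + Poisson(lambda_i (1 - p_i))`; for `n_i = 0`,
#' a structural zero with posterior probability
#' `(1 - psi) / ((1 - psi) + psi e^{-lambda_i p_i})`, else
#' `Poisson(lambda_i (1 - p_i))`.  Every draw satisfies `N_i >= n_i`.
#'
#' @param fit A [fit_bnmm()] result.
#' @param draw_ids Draw indices (default: all retained draws).
#' @param seed Optional seed.
#' @return Integer matrix, `length(draw_ids)` rows by segments.
#' @export
latent_counts <- function(fit, draw_ids = seq_len(nrow(fit$draws)),
                          seed = NULL) {
  stopifnot(inherits(fit, "bnmm_fit"))
  if (!is.null(seed)) set.seed(seed)
  md <- fit$data
  out <- matrix(NA_integer_, length(draw_ids), md$n_seg)
  for (r in seq_along(draw_ids)) {
    pars <- draw_params(fit, draw_ids[r])
    mu_full <- pars$lambda                    # includes tau
    p_i <- pars$p_i
    N <- integer(md$n_seg)
    pos <- md$n > 0L
    N[pos] <- md$n[pos] + stats::rpois(sum(pos),
                                       mu_full[pos] * (1 - p_i[pos]))
    if (any(!pos)) {
      w_struct <- (1 - pars$psi) /
        ((1 - pars$psi) + pars$psi * exp(-mu_full[!pos] * p_i[!pos]))
      occ <- stats::runif(sum(!pos)) >= w_struct
      N0 <- integer(sum(!pos))
      N0[occ] <- stats::rpois(sum(occ),
                              (mu_full[!pos] * (1 - p_i[!pos]))[occ])
      N[!pos] <- N0
    }
    out[r, ] <- N
  }
  out
}

# Expand one retained draw into the segment-level quantities the checks
# and predictions need.
draw_params <- function(fit, draw_id) {
  d <- fit$draws[draw_id, ]
  md <- fit$data
  beta <- if (length(fit$covariates))
    d[paste0("beta_", fit$covariates)] else numeric(0)
  psi <- if (fit$zero_inflation) d[["psi"]] else 1
  tau <- if (!is.null(fit$tau)) fit$tau[draw_id, ] else numeric(md$n_seg)
  p_i <- if (is.null(fit$p_fixed)) {
    alpha <- d[paste0("alpha_", colnames(md$Yu))]
    sigma_c <- as.numeric(exp(md$Yu %*% alpha))
    mean_detection_probability(sigma_c, md$W)[md$class_id]
  } else rep(fit$p_fixed, md$n_seg)
  eta <- d[["beta0"]] + if (length(beta)) drop(md$X %*% beta) else 0
  list(beta0 = d[["beta0"]], beta = beta, psi = psi,
       sigma_tau = if (fit$re_tau) d[["sigma_tau"]] else 0,
       tau = tau, p_i = p_i, lambda = md$A * exp(eta + tau))
}

#' Posterior for the group-size distribution's mean and variance
#'
#' Observed group sizes (minimum 1) are modelled as a shifted negative
#' binomial: `size - 1 ~ NegBin(mu, dispersion)`.  An adaptive
#' random-walk Metropolis sampler with a `Normal(0, 3)` prior on
#' `log mu` and a `Gamma(2, 0.5)` prior on the dispersion (which keeps
#' the sampler off the `dispersion -> 0` ridge where the negative
#' binomial fits any all-ones sample equally well at arbitrary `mu`)
#' yields posterior draws of the distribution's mean `1 + mu` and
#' variance `mu + mu^2 / dispersion`, aligned count-wise with the
#' count-model posterior so abundance can propagate both uncertainties
#' jointly.
#'
#' @param sizes Integer group sizes, all >= 1 (>= 2 values).
#' @param n_draws Number of posterior draws to return.
#' @param iter,burnin Sampler protocol.
#' @param seed Integer seed.
#' @return Object of class `group_size_post`: `draws` (matrix with
#'   columns `mean`, `variance`) and `summary`.
#' @export
group_size_summary <- function(sizes, n_draws = 1800, iter = 6000,
                               burnin = 2000, seed = 1) {
  if (length(sizes) < 2L) stop_("need at least 2 observed group sizes")
  if (any(sizes < 1)) stop_("group sizes must be >= 1")
  set.seed(seed)
  x <- as.integer(sizes) - 1L
  lpost <- function(th) {
    sum(stats::dnbinom(x, mu = exp(th[1]), size = exp(th[2]),
                       log = TRUE)) +
      stats::dnorm(th[1], 0, 3, log = TRUE) +
      stats::dgamma(exp(th[2]), shape = 2, rate = 0.5, log = TRUE) +
      th[2]                                  # Jacobian of log dispersion
  }
  th <- c(log(max(mean(x), 0.05)), 0)
  log_sd <- rep(log(0.3), 2)
  cur <- lpost(th)
  keep <- matrix(NA_real_, iter - burnin, 2)
  for (t in seq_len(iter)) {
    gam <- if (t <= burnin) min(0.25, 3 / sqrt(t)) else 0
    for (j in 1:2) {
      prop <- th
      prop[j] <- th[j] + exp(log_sd[j]) * stats::rnorm(1)
      lp <- lpost(prop)
      a <- exp(min(0, lp - cur))
      if (stats::runif(1) < a) { th <- prop; cur <- lp }
      log_sd[j] <- log_sd[j] + gam * (a - 0.44)
    }
    if (t > burnin) keep[t - burnin, ] <- th
  }
  idx <- round(seq(1, nrow(keep), length.out = n_draws))
  mu <- exp(keep[idx, 1]); k <- exp(keep[idx, 2])
  draws <- cbind(mean = 1 + mu, variance = mu + mu^2 / k)
  structure(list(draws = draws,
                 summary = t(apply(draws, 2L, post_summary)),
                 n_obs = length(sizes)),
            class = "group_size_post")
}

#' @export
print.group_size_post <- function(x, ...) {
  cat("Group-size posterior (shifted negative binomial),",
      x$n_obs, "groups\n")
  print(x$summary, digits = 3)
  invisible(x)
}
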