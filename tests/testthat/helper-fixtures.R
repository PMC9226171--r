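# Shared fixtures: all synthetic, generated in code at test time.

# Fabricated segment table (no trackline walk needed) with a single
# detection class and unit covariate handling.
make_segments <- function(n, L = 10, wave = 0, wind = 0, sea = 0,
                          x = NULL, y = NULL) {
  data.frame(segment_id = seq_len(n),
             x_mid = x %||% runif(n, 0, 140),
             y_mid = y %||% runif(n, 0, 140),
             length_km = rep_len(L, n),
             wave_bin = rep_len(wave, n), wind_bin = rep_len(wind, n),
             sea_bin = rep_len(sea, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A minimal bnmm_fit-shaped object whose posterior is a point mass at
# known parameters; lets the checking machinery run against exact truth
# without an MCMC fit.
point_mass_fit <- function(segments, sightings, W, covariates,
                           beta0, beta = numeric(0), psi = 1,
                           alpha = c(0, 0, 0, 0), sigma_tau = 0,
                           tau = NULL, n_draws = 200) {
  md <- nmixds:::build_model_data(segments, sightings, W, covariates)
  cols <- c("beta0", if (length(covariates)) paste0("beta_", covariates),
            "psi", paste0("alpha_", colnames(md$Yu)), "sigma_tau")
  row <- c(beta0, beta, psi, alpha, sigma_tau)
  draws <- matrix(rep(row, each = n_draws), n_draws,
                  dimnames = list(NULL, cols))
  tau_mat <- matrix(rep(tau %||% numeric(md$n_seg), each = n_draws),
                    n_draws)
  structure(list(draws = draws, tau = tau_mat,
                 chain = rep(1L, n_draws),
                 iteration = seq_len(n_draws),
                 rhat = setNames(rep(1, length(cols)), cols),
                 converged = TRUE, data = md, covariates = covariates,
                 W = W, re_tau = sigma_tau > 0 || !is.null(tau),
                 zero_inflation = TRUE, p_fixed = NULL,
                 protocol = list(chains = 1, iter = n_draws, burnin = 0,
                                 thin = 1, retained = n_draws)),
            class = "bnmm_fit")
}

# Simulate observed counts directly from the generative chain at given
# parameters (single detection class), returning counts + sightings.
simulate_obs <- function(segments, W, beta0, X = NULL,
                         beta = numeric(0), psi = 1, sigma = 1,
                         sigma_tau = 0) {
  n <- nrow(segments)
  tau <- if (sigma_tau > 0) rnorm(n, 0, sigma_tau) else numeric(n)
  eta <- beta0 + if (length(beta)) drop(X %*% beta) else 0
  lambda <- 2 * W * segments$length_km * exp(eta + tau)
  occ <- runif(n) < psi
  N <- ifelse(occ, rpois(n, lambda), 0L)
  sightings <- do.call(rbind, lapply(which(N > 0), function(i) {
    y <- runif(N[i], 0, W)
    keep <- runif(N[i]) < exp(-y^2 / (2 * sigma^2))
    if (!any(keep)) return(NULL)
    data.frame(segment_id = segments$segment_id[i],
               perp_dist_km = y[keep])
  }))
  if (is.null(sightings))
    sightings <- data.frame(segment_id = integer(0),
                            perp_dist_km = numeric(0))
  sightings$sighting_id <- seq_len(nrow(sightings))
  segments$n <- tabulate(match(sightings$segment_id,
                               segments$segment_id), nbins = n)
  list(segments = segments, sightings = sightings, N = N, tau = tau)
}

# Independent oracle: ZIP pmf summed against the binomial by brute force.
zip_binom_marginal <- function(n, lambda, p, psi, Nmax = 500) {
  Ns <- n:Nmax
  pmf <- psi * dpois(Ns, lambda)
  pmf[Ns == 0] <- pmf[Ns == 0] + (1 - psi)
  sum(pmf * dbinom(n, Ns, p))
}

# Brute-force joint log likelihood (truncated latent sum + quadrature
# normalizers), fully independent of the package's marginalized path.
brute_force_loglik <- function(segs, sgt, X, params, W) {
  n_seg <- nrow(segs)
  Ydet <- cbind(1, segs$wave_bin, segs$wind_bin, segs$sea_bin)
  sig <- exp(drop(Ydet %*% params$alpha))
  lam <- 2 * W * segs$length_km *
    exp(params$beta0 + (if (length(params$beta)) drop(X %*% params$beta)
                        else 0) + params$tau)
  p <- vapply(seq_len(n_seg), function(i)
    integrate(function(y) exp(-y^2 / (2 * sig[i]^2)), 0, W,
              rel.tol = 1e-13)$value / W, numeric(1))
  count_ll <- sum(vapply(seq_len(n_seg), function(i)
    log(zip_binom_marginal(segs$n[i], lam[i], p[i], params$psi)),
    numeric(1)))
  dist_ll <- if (nrow(sgt)) sum(vapply(seq_len(nrow(sgt)), function(d) {
    i <- match(sgt$segment_id[d], segs$segment_id)
    z <- integrate(function(y) exp(-y^2 / (2 * sig[i]^2)), 0, W,
                   rel.tol = 1e-13)$value
    -sgt$perp_dist_km[d]^2 / (2 * sig[i]^2) - log(z)
  }, numeric(1))) else 0
  count_ll + dist_ll
}

# One moderately sized fitted model, reused by several test files.
.fit_cache <- new.env(parent = emptyenv())
get_test_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    sv <- simulate_survey(sim_config(seed = 11, n_transects = 50))
    .fit_cache$survey <- sv
    .fit_cache$fit <- suppressWarnings(
      fit_bnmm(sv$segments, sv$sightings, W = sv$config$truncation_W,
               covariates = names(sv$config$true_beta),
               chains = 2, iter = 2400, burnin = 1200, thin = 2,
               seed = 5))
  }
  .fit_cache$fit
}
get_test_survey <- function() {
  get_test_fit()
  .fit_cache$survey
}
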