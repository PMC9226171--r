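test_that("count part of the likelihood: Poisson zero case", {
  segs <- make_segments(1, L = 8)
  segs$n <- 0L
  sgt <- data.frame(segment_id = integer(0), perp_dist_km = numeric(0))
  W <- 2.5
  alpha <- c(log(1.3), -0.2, 0, 0)
  params <- list(beta0 = -2, beta = numeric(0), psi = 1, alpha = alpha,
                 sigma_tau = 0)
  lam <- 2 * W * 8 * exp(-2)
  p <- mean_detection_probability(exp(alpha[1]), W)
  expect_equal(joint_log_likelihood(params, segs, sgt, W), -lam * p,
               tolerance = 1e-12)
})

test_that("marginalized likelihood equals the truncated-sum oracle", {
  set.seed(101)
  W <- 2.5
  for (rep in 1:20) {
    n_seg <- 4
    segs <- make_segments(n_seg, L = runif(n_seg, 2, 10),
                          wave = rbinom(n_seg, 1, 0.4),
                          wind = rbinom(n_seg, 1, 0.4),
                          sea = rbinom(n_seg, 1, 0.4))
    X <- matrix(rnorm(n_seg * 2), n_seg, 2,
                dimnames = list(NULL, c("sst", "chl")))
    segs <- cbind(segs, X)
    n_i <- rpois(n_seg, 1.2)
    sgt <- data.frame(
      segment_id = rep(segs$segment_id, n_i),
      perp_dist_km = runif(sum(n_i), 0, W))
    segs$n <- n_i
    params <- list(beta0 = runif(1, -4, -2), beta = rnorm(2, 0, 0.5),
                   psi = runif(1, 0.3, 1),
                   alpha = c(runif(1, -0.5, 0.7), rnorm(3, 0, 0.3)),
                   sigma_tau = 0.4, tau = rnorm(n_seg, 0, 0.4))
    got <- joint_log_likelihood(params, segs, sgt, W, c("sst", "chl"),
                                include_tau_prior = FALSE)
    expect_lt(abs(got - brute_force_loglik(segs, sgt, X, params, W)),
              1e-8)
  }
})

test_that("a distance at W under flat detection adds log(1/W)", {
  W <- 2.5
  segs <- make_segments(1, L = 10)
  segs$n <- 1L
  sgt <- data.frame(segment_id = 1L, perp_dist_km = W)
  params <- list(beta0 = -2, beta = numeric(0), psi = 1,
                 alpha = c(log(1e4 * W), 0, 0, 0), sigma_tau = 0)
  with_s <- joint_log_likelihood(params, segs, sgt, W)
  segs0 <- segs; segs0$n <- 0L
  sgt0 <- sgt[0, ]
  without <- joint_log_likelihood(params, segs0, sgt0, W)
  # count parts differ too; isolate the distance term
  lam_p <- 2 * W * 10 * exp(-2) *
    mean_detection_probability(1e4 * W, W)
  count_delta <- dpois(1, lam_p, log = TRUE) - (-lam_p)
  expect_equal(with_s - without - count_delta, log(1 / W),
               tolerance = 1e-6)
})

test_that("likelihood is invariant under segment reordering", {
  sv <- get_test_survey()
  segs <- sv$segments
  params <- list(beta0 = -3.5, beta = c(0.4, -0.2), psi = 0.8,
                 alpha = c(0, -0.4, -0.3, -0.2), sigma_tau = 0)
  base <- joint_log_likelihood(params, segs, sv$sightings, 2.5,
                               c("sst", "chl"))
  set.seed(1)
  perm <- sample(nrow(segs))
  expect_equal(joint_log_likelihood(params, segs[perm, ], sv$sightings,
                                    2.5, c("sst", "chl")),
               base, tolerance = 1e-10)
})

test_that("inconsistent counts and unknown segments are rejected", {
  segs <- make_segments(2); segs$n <- c(1L, 0L)
  sgt <- data.frame(segment_id = 2L, perp_dist_km = 0.5)
  params <- list(beta0 = -2, beta = numeric(0), psi = 1,
                 alpha = c(0, 0, 0, 0), sigma_tau = 0)
  expect_error(joint_log_likelihood(params, segs, sgt, 2.5),
               "inconsistent")
  sgt_bad <- data.frame(segment_id = 9L, perp_dist_km = 0.5)
  expect_error(joint_log_likelihood(params, segs, sgt_bad, 2.5),
               "unknown segment")
})

test_that("retained draw bookkeeping follows chains, burn-in and thinning", {
  fit <- get_test_fit()
  expect_equal(nrow(fit$draws),
               mcmc_retained(2, 2400, 1200, 2))
  expect_equal(fit$protocol$retained, nrow(fit$draws))
  expect_equal(table(fit$chain), table(rep(1:2, each = 600)),
               ignore_attr = TRUE)
})

test_that("reconstructed latent counts dominate observed counts", {
  fit <- get_test_fit()
  N <- latent_counts(fit, draw_ids = seq(1, nrow(fit$draws), by = 40),
                     seed = 1)
  expect_true(all(t(N) >= fit$data$n))
  expect_true(all(N >= 0))
})

test_that("with p = 1 and psi = 1 the posterior matches Poisson regression", {
  set.seed(55)
  n <- 300
  segs <- make_segments(n, L = runif(n, 4, 10))
  X <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("sst", "chl")))
  segs <- cbind(segs, X)
  obs <- simulate_obs(segs, W = 2.5, beta0 = -3.2, X = X,
                      beta = c(0.5, -0.3), psi = 1, sigma = 1e6)
  fit <- suppressWarnings(
    fit_bnmm(obs$segments, obs$sightings, W = 2.5,
             covariates = c("sst", "chl"), chains = 2, iter = 2000,
             burnin = 1000, thin = 2, seed = 2, re_tau = FALSE,
             zero_inflation = FALSE, p_fixed = 1))
  glm_fit <- glm(obs$segments$n ~ X + offset(log(2 * 2.5 *
                                                   segs$length_km)),
                 family = poisson)
  co <- summary(glm_fit)$coefficients
  post <- summary(fit)
  for (j in 1:3) {
    comb_sd <- sqrt(post$sd[j]^2 + co[j, "Std. Error"]^2)
    expect_lt(abs(post$mean[j] - co[j, "Estimate"]), 2 * comb_sd)
  }
})

test_that("without overdispersion the random-effect SD shrinks to zero", {
  set.seed(66)
  n <- 1000
  segs <- make_segments(n, L = runif(n, 4, 10))
  X <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "sst"))
  segs <- cbind(segs, X)
  obs <- simulate_obs(segs, W = 2.5, beta0 = -3.3, X = X, beta = 0.4,
                      psi = 0.85, sigma = 1, sigma_tau = 0)
  fit <- suppressWarnings(
    fit_bnmm(obs$segments, obs$sightings, W = 2.5, covariates = "sst",
             chains = 1, iter = 2600, burnin = 1300, thin = 2, seed = 3))
  expect_lt(median(fit$draws[, "sigma_tau"]), 0.2)
})

test_that("an all-ones size sample degenerates the size posterior", {
  gs <- group_size_summary(rep(1L, 60), n_draws = 500, iter = 3000,
                           burnin = 1000, seed = 1)
  expect_lt(abs(mean(gs$draws[, "mean"]) - 1), 0.05)
  expect_lt(mean(gs$draws[, "variance"]), 0.1)
})

test_that("size posterior mean matches a quadrature oracle on {1,1,2,2}", {
  sizes <- c(1, 1, 2, 2)
  # brute-force posterior by 2-D grid quadrature on (log mu, log k)
  lmu <- seq(-9, 3, length.out = 240)
  lk <- seq(-6, 9, length.out = 240)
  grid <- expand.grid(lmu = lmu, lk = lk)
  lp <- vapply(seq_len(nrow(grid)), function(i) {
    sum(dnbinom(sizes - 1, mu = exp(grid$lmu[i]), size = exp(grid$lk[i]),
                log = TRUE)) +
      dnorm(grid$lmu[i], 0, 3, log = TRUE) +
      dgamma(exp(grid$lk[i]), shape = 2, rate = 0.5, log = TRUE) +
      grid$lk[i]
  }, numeric(1))
  wts <- exp(lp - max(lp)); wts <- wts / sum(wts)
  oracle_mean <- sum((1 + exp(grid$lmu)) * wts)
  gs <- group_size_summary(sizes, n_draws = 4000, iter = 12000,
                           burnin = 3000, seed = 2)
  expect_lt(abs(mean(gs$draws[, "mean"]) - oracle_mean), 0.1)
})

test_that("negative binomial sizes are recovered within posterior spread", {
  set.seed(9)
  hits <- 0
  for (r in 1:10) {
    sizes <- 1L + rnbinom(300, mu = 17.6, size = 2)
    gs <- group_size_summary(sizes, n_draws = 1000, iter = 3000,
                             burnin = 1000, seed = r)
    m <- gs$summary["mean", ]
    hits <- hits + (abs(m[["mean"]] - 18.6) <= 2 * m[["sd"]])
  }
  expect_gte(hits, 9)
})

test_that("empty or invalid size input is rejected", {
  expect_error(group_size_summary(integer(0)), "at least 2")
  expect_error(group_size_summary(c(0, 2)), ">= 1")
})
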