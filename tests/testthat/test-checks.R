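# A small consistent data set + point-mass "posterior" at known
# parameters, shared by the checking tests.
make_truth_fit <- function(n_seg = 100, beta0 = -2.8, psi = 0.8,
                           sigma = 1, W = 2.5, n_draws = 100,
                           seed = 1) {
  set.seed(seed)
  segs <- make_segments(n_seg, L = runif(n_seg, 4, 10))
  obs <- simulate_obs(segs, W = W, beta0 = beta0, psi = psi,
                      sigma = sigma)
  point_mass_fit(obs$segments, obs$sightings, W, character(),
                 beta0 = beta0, psi = psi,
                 alpha = c(log(sigma), 0, 0, 0), n_draws = n_draws)
}

# The generative law, written independently of the package internals.
sim_true_counts <- function(lambda, p, psi) {
  occ <- runif(length(lambda)) < psi
  rbinom(length(lambda), ifelse(occ, rpois(length(lambda), lambda), 0L), p)
}

test_that("replicate means track the expected counts psi*lambda*p", {
  fit <- make_truth_fit(n_seg = 120, n_draws = 400)
  reps <- posterior_replicates(fit, 400, seed = 2)
  expected <- attr(reps, "expected")
  per_seg_mean <- rowMeans(reps)
  e <- rowMeans(expected)
  se <- sqrt(e / 400) + 1e-3    # Poisson-scale MC error bound
  expect_gt(mean(abs(per_seg_mean - e) < 5 * se), 0.95)
  expect_lt(abs(mean(per_seg_mean) - mean(e)), 4 * sqrt(mean(e) / (400 * 120)))
})

test_that("a psi = 0 point-mass posterior replicates all zeros", {
  set.seed(3)
  segs <- make_segments(30)
  segs$n <- 0L
  sgt <- data.frame(segment_id = integer(0), perp_dist_km = numeric(0))
  fit <- point_mass_fit(segs, sgt, 2.5, character(), beta0 = -2,
                        psi = 0, n_draws = 50)
  reps <- posterior_replicates(fit, 50, seed = 1)
  expect_true(all(reps == 0))
  # ...and the chi-squared tie convention then gives a Bayesian p of 1
  ppc <- posterior_predictive_chisq(fit, n_draws = 50, seed = 1)
  expect_equal(ppc$bayes_p, 1)
})

test_that("posterior replication is reproducible under a seed", {
  fit <- make_truth_fit(n_seg = 40, n_draws = 60)
  r1 <- posterior_replicates(fit, 60, seed = 9)
  r2 <- posterior_replicates(fit, 60, seed = 9)
  expect_identical(r1, r2)
})

test_that("scaled residuals sit at the extremes when data do", {
  reps <- matrix(rpois(50 * 200, 5) + 2L, 50, 200)
  res_low <- scaled_residuals(rep(0L, 50), reps, seed = 1)
  expect_true(all(res_low < 1 / 201))
  res_high <- scaled_residuals(rep(1000L, 50), reps, seed = 1)
  expect_true(all(res_high > 200 / 201))
})

test_that("tied observations get uniform jitter across (0, 1)", {
  reps <- matrix(3L, 500, 100)         # constant replicates
  res <- scaled_residuals(rep(3L, 500), reps, seed = 4)
  expect_true(all(res > 0 & res < 1))
  expect_gt(suppressWarnings(ks.test(res, "punif"))$p.value, 0.01)
})

test_that("scaled residuals are calibrated under the true model", {
  fit <- make_truth_fit(n_seg = 100, n_draws = 100, seed = 10)
  lambda <- nmixds:::draw_params(fit, 1)$lambda
  p <- nmixds:::draw_params(fit, 1)$p_i
  set.seed(11)
  rejections <- 0
  for (trial in 1:100) {
    reps <- posterior_replicates(fit, 100)
    obs <- sim_true_counts(lambda, p, 0.8)
    res <- scaled_residuals(obs, reps)
    ks_p <- suppressWarnings(ks.test(res, "punif"))$p.value
    rejections <- rejections + (ks_p < 0.05)
  }
  expect_lte(rejections, 7)
})

test_that("dispersion ratio is near 1 for well-matched data", {
  fit <- make_truth_fit(n_seg = 200, n_draws = 200, seed = 12)
  lambda <- nmixds:::draw_params(fit, 1)$lambda
  p <- nmixds:::draw_params(fit, 1)$p_i
  set.seed(13)
  reps <- posterior_replicates(fit, 200)
  obs <- sim_true_counts(lambda, p, 0.8)
  tests <- residual_tests(scaled_residuals(obs, reps), obs, reps)
  expect_gt(tests$dispersion_ratio, 0.7)
  expect_lt(tests$dispersion_ratio, 1.4)
  expect_gt(tests$dispersion_p, 0.01)
})

test_that("the dispersion test detects unmodelled overdispersion", {
  # data carry a lognormal random effect; the replicating model does not
  set.seed(14)
  n_seg <- 150
  segs <- make_segments(n_seg, L = 8)
  obs0 <- simulate_obs(segs, W = 2.5, beta0 = -2.5, psi = 1, sigma = 1)
  sigma_re <- 1
  fit <- point_mass_fit(obs0$segments, obs0$sightings, 2.5, character(),
                        beta0 = -2.5 + sigma_re^2 / 2, psi = 1,
                        alpha = c(0, 0, 0, 0), n_draws = 100)
  lambda0 <- 2 * 2.5 * segs$length_km * exp(-2.5)
  p <- nmixds:::draw_params(fit, 1)$p_i
  hits <- 0
  for (trial in 1:50) {
    lam <- lambda0 * exp(rnorm(n_seg, 0, sigma_re))
    obs <- rbinom(n_seg, rpois(n_seg, lam), p)
    reps <- posterior_replicates(fit, 100)
    tests <- residual_tests(scaled_residuals(obs, reps), obs, reps)
    hits <- hits + (tests$dispersion_p < 0.05 & tests$dispersion_ratio > 1)
  }
  expect_gte(hits, 40)
})

test_that("all-zero observed and replicated data agree on 100% zeros", {
  res <- residual_tests(runif(20), rep(0L, 20),
                        matrix(0L, 20, 100))
  expect_equal(res$pct_zeros_observed, 100)
  expect_true(all(res$pct_zeros_simulated == 100))
})

test_that("inflated counts drive the Bayesian p to 0 and c-hat above 1", {
  fit <- make_truth_fit(n_seg = 150, n_draws = 150, seed = 16)
  inflated <- fit
  inflated$data$n <- as.integer(fit$data$n * 5L)
  ppc <- posterior_predictive_chisq(inflated, n_draws = 150, seed = 1)
  expect_lt(ppc$bayes_p, 0.05)
  expect_gt(ppc$c_hat, 1)
})

test_that("Moran's I matches a brute-force double loop", {
  set.seed(17)
  n <- 12
  coords <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  r <- rnorm(n)
  got <- morans_i(r, coords, n_perm = 99, seed = 1)
  # O(n^2) oracle
  d <- as.matrix(dist(coords))
  w <- 1 / d; diag(w) <- 0
  rc <- r - mean(r)
  num <- 0; wsum <- 0
  for (i in 1:n) for (j in 1:n) {
    num <- num + w[i, j] * rc[i] * rc[j]
    wsum <- wsum + w[i, j]
  }
  oracle <- n / wsum * num / sum(rc^2)
  expect_lt(abs(got$statistic - oracle), 1e-12)
  expect_equal(got$expectation, -1 / (n - 1))
})

test_that("permutation distribution is centred at -1/(n-1)", {
  set.seed(18)
  n <- 30
  coords <- cbind(runif(n), runif(n))
  r <- rnorm(n)
  Is <- replicate(600, morans_i(sample(r), coords, n_perm = 0,
                                seed = NULL)$statistic)
  expect_lt(abs(mean(Is) - (-1 / (n - 1))), 4 * sd(Is) / sqrt(600))
})

test_that("Moran's I detects a strong residual gradient", {
  set.seed(19)
  n <- 100
  hits <- 0
  for (trial in 1:50) {
    coords <- cbind(runif(n, 0, 50), runif(n, 0, 50))
    r <- coords[, 1] / 50 + rnorm(n, 0, 0.15)
    m <- morans_i(r, coords, n_perm = 499)
    hits <- hits + (m$p_value < 0.01)
  }
  expect_gte(hits, 48)
})

test_that("coincident points are handled by the weight cap", {
  coords <- rbind(cbind(rep(1, 3), rep(1, 3)),
                  cbind(runif(9, 2, 5), runif(9, 2, 5)))
  r <- rnorm(12)
  m <- morans_i(r, coords, n_perm = 49, seed = 2)
  expect_true(is.finite(m$statistic))
})

test_that("the assembled report carries every battery field", {
  fit <- get_test_fit()
  rep_count <- 150
  chk <- check_model(fit, n_rep = rep_count, n_perm = 199, seed = 3)
  expect_s3_class(chk, "bnmm_checks")
  expect_true(chk$bayes_p >= 0 && chk$bayes_p <= 1)
  expect_gt(chk$c_hat, 0)
  expect_true(all(chk$residuals >= 0 & chk$residuals <= 1))
  expect_true(is.finite(chk$morans_i))
})
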