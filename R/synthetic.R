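# Synthetic survey generator.
#
# Emulates the statistical structure the hierarchical count model assumes:
# effort split into <= 10 km segments with smooth environmental fields at
# the segment midpoints, zero-inflated Poisson latent group counts with an
# effort-area offset and observation-level overdispersion, groups placed
# uniformly in perpendicular distance within the truncation strip and
# thinned by a half-normal detection function driven by binary
# sea-condition covariates, and daily vessel pings clustered around ports.
# Everything downstream of raw data acquisition is testable against this
# generator because the generative parameters are known exactly.

#' Configuration for the synthetic survey generator
#'
#' Defaults describe a mid-density cetacean survey on a 140 x 140 km
#' planar grid: about 0.02 groups per km2 at baseline conditions, 75%
#' zero-inflation occupancy, a 1 km baseline detection scale with poorer
#' sea conditions shrinking it, and modest segment-level overdispersion.
#'
#' @param grid_extent Numeric length-2, grid extent in km (x, y); must be
#'   whole multiples of `cell_size`.
#' @param cell_size Grid cell edge, km.
#' @param n_transects Number of survey tracklines.
#' @param target_segment_length Segment cut length, km.
#' @param truncation_W Truncation (strip half-width), km.
#' @param true_beta0 Intercept of the log group-density (log groups/km2 at
#'   mean covariates, baseline conditions).
#' @param true_beta Named vector of environmental coefficients; the names
#'   define the simulated covariate fields.
#' @param true_psi Probability that a segment is in the non-zero
#'   (occupied) component of the zero-inflated Poisson.
#' @param true_alpha Detection coefficients on log sigma:
#'   `(intercept, wave_bin, wind_bin, sea_bin)`.
#' @param sigma_tau SD of the per-segment normal random effect on the log
#'   mean (observation-level overdispersion).
#' @param group_size_mean,group_size_dispersion Mean (>= 1) and negative
#'   binomial dispersion of the shifted (minimum 1) group-size
#'   distribution.
#' @param n_vessels,n_days Vessel-track simulation size.
#' @param ports Data frame with columns `name, x, y, fleet` of port
#'   locations inside the grid; `NULL` for two defaults.
#' @param seed Integer seed; identical configurations reproduce identical
#'   surveys byte for byte.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(grid_extent = c(140, 140),
                       cell_size = 7,
                       n_transects = 20,
                       target_segment_length = 10,
                       truncation_W = 2.5,
                       true_beta0 = -3.9,
                       true_beta = c(sst = 0.5, chl = -0.3),
                       true_psi = 0.75,
                       true_alpha = c(0, -0.5, -0.4, -0.3),
                       sigma_tau = 0.3,
                       group_size_mean = 2,
                       group_size_dispersion = 1.5,
                       n_vessels = 25,
                       n_days = 40,
                       ports = NULL,
                       seed = 1L) {
  if (length(grid_extent) != 2L || any(!is.finite(grid_extent)) ||
      any(grid_extent <= 0))
    stop_("invalid configuration: 'grid_extent' must be two positive numbers")
  check_number(cell_size, "cell_size", lower = 0, strict = TRUE)
  check_number(truncation_W, "truncation_W", lower = 0, strict = TRUE)
  check_number(true_psi, "true_psi", lower = 0, upper = 1)
  check_number(sigma_tau, "sigma_tau", lower = 0)
  check_number(group_size_mean, "group_size_mean", lower = 1)
  ncells <- grid_extent / cell_size
  if (any(abs(ncells - round(ncells)) > 1e-8))
    stop_("invalid configuration: 'grid_extent' must be whole multiples of 'cell_size'")
  if (is.null(names(true_beta)) || any(names(true_beta) == ""))
    stop_("'true_beta' must be a named vector (names define covariates)")
  if (length(true_alpha) != 4L)
    stop_("'true_alpha' must be (intercept, wave, wind, sea)")
  if (is.null(ports)) {
    ports <- data.frame(
      name = c("north", "south"),
      x = c(0.15, 0.25) * grid_extent[1],
      y = c(0.8, 0.2) * grid_extent[2],
      stringsAsFactors = FALSE)
  }
  structure(list(
    grid_extent = grid_extent, cell_size = cell_size,
    n_transects = as.integer(n_transects),
    target_segment_length = target_segment_length,
    truncation_W = truncation_W,
    true_beta0 = true_beta0, true_beta = true_beta, true_psi = true_psi,
    true_alpha = true_alpha, sigma_tau = sigma_tau,
    group_size_mean = group_size_mean,
    group_size_dispersion = group_size_dispersion,
    n_vessels = as.integer(n_vessels), n_days = as.integer(n_days),
    ports = ports, seed = as.integer(seed)
  ), class = "sim_config")
}

# Gaussian-kernel low-pass smoother for a cells matrix (ny rows, nx cols).
smooth_field <- function(m, bandwidth_cells = 3) {
  kern <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-d^2 / (2 * bandwidth_cells^2))
    k / rowSums(k)
  }
  kern(nrow(m)) %*% m %*% t(kern(ncol(m)))
}

#' Simulate smooth environmental covariate fields
#'
#' Low-pass-filtered Gaussian noise, one field per name in
#' `config$true_beta`, centred and scaled to mean 0, sd 1 over cells.
#' Fields listed in `constant` are returned as-is (value 0) and flagged:
#' scaling a zero-variance field is undefined.
#'
#' @param config A [sim_config].
#' @param constant Character vector of field names to generate as
#'   degenerate constant fields.
#' @return A [cov_grid] with one covariate column per field and a logical
#'   `zero_variance` attribute per field.
#' @export
simulate_environment <- function(config, constant = character()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  nx <- as.integer(round(config$grid_extent[1] / config$cell_size))
  ny <- as.integer(round(config$grid_extent[2] / config$cell_size))
  nms <- names(config$true_beta)
  vals <- matrix(NA_real_, nx * ny, length(nms), dimnames = list(NULL, nms))
  zero_var <- stats::setNames(logical(length(nms)), nms)
  for (j in seq_along(nms)) {
    if (nms[j] %in% constant) {
      vals[, j] <- 0
      zero_var[j] <- TRUE
      next
    }
    f <- smooth_field(matrix(stats::rnorm(nx * ny), ny, nx))
    f <- t(f)                                   # row-major cell order
    vals[, j] <- (f - mean(f)) / stats::sd(f)
  }
  grid <- cov_grid(nx, ny, config$cell_size, covariates = vals)
  attr(grid, "zero_variance") <- zero_var
  grid
}

#' Simulate survey tracklines with sea-condition records
#'
#' Straight east-west tracklines at random offsets, discretized to ~1 km
#' vertices, each carrying the raw observational conditions (wave height
#' m, wind speed kn, Beaufort sea state) recorded when effort started, and
#' a survey date drawn from summer/autumn/spring months.
#'
#' @param config A [sim_config].
#' @return Data frame: `track_id, x, y, date, wave_m, wind_kn,
#'   sea_beaufort`.
#' @export
simulate_tracklines <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  ext <- config$grid_extent
  months <- c(1, 4, 10)
  out <- vector("list", config$n_transects)
  for (k in seq_len(config$n_transects)) {
    len <- stats::runif(1, 15, min(55, ext[1] - 1))
    x0 <- stats::runif(1, 0, ext[1] - len)
    y0 <- stats::runif(1, 0.02, 0.98) * ext[2]
    xs <- seq(x0, x0 + len, by = 1)
    if (xs[length(xs)] < x0 + len) xs <- c(xs, x0 + len)
    date <- as.Date(sprintf("%d-%02d-%02d", sample(2018:2020, 1),
                            sample(months, 1), sample(1:28, 1)))
    out[[k]] <- data.frame(
      track_id = k, x = xs, y = y0, date = date,
      wave_m = round(stats::rlnorm(1, log(1.4), 0.5), 2),
      wind_kn = round(stats::rgamma(1, shape = 4, scale = 3.5), 1),
      sea_beaufort = sample(0:3, 1, prob = c(0.2, 0.35, 0.3, 0.15)))
  }
  do.call(rbind, out)
}

#' Simulate latent group counts on effort segments
#'
#' Zero-inflated Poisson: with probability `1 - psi` a segment's latent
#' group count `N_i` is a structural zero; otherwise
#' `N_i ~ Poisson(2 W L_i exp(beta0 + X_i beta + tau_i))` with
#' `tau_i ~ Normal(0, sigma_tau^2)` and the searched strip area
#' `2 W L_i` (km2) acting as the effort offset.  One group size is drawn
#' per latent group from the shifted negative binomial.
#'
#' @param config A [sim_config].
#' @param segments Segment table with `segment_id, x_mid, y_mid,
#'   length_km`.
#' @param covariates A [cov_grid] carrying every field named in
#'   `config$true_beta`.
#' @return List: `N` (latent counts), `tau`, `occupied` (zero-inflation
#'   indicator), `X` (covariate matrix at midpoints), `lambda`, and
#'   `groups` (data frame `segment_id, group_size`, one row per latent
#'   group).
#' @export
simulate_counts <- function(config, segments, covariates) {
  stopifnot(inherits(config, "sim_config"), inherits(covariates, "cov_grid"))
  set.seed(config$seed + 3L)
  if (any(segments$length_km <= 0 |
          segments$length_km > config$target_segment_length + 1e-9))
    stop_("segment lengths must lie in (0, target_segment_length]")
  X <- extract_covariates(segments, covariates,
                          names(config$true_beta))
  n <- nrow(segments)
  tau <- if (config$sigma_tau > 0)
    stats::rnorm(n, 0, config$sigma_tau) else numeric(n)
  lambda <- 2 * config$truncation_W * segments$length_km *
    exp(config$true_beta0 + drop(X %*% config$true_beta) + tau)
  occupied <- stats::runif(n) < config$true_psi
  N <- ifelse(occupied, stats::rpois(n, lambda), 0L)
  sizes <- if (sum(N) > 0)
    1L + stats::rnbinom(sum(N), mu = config$group_size_mean - 1,
                        size = config$group_size_dispersion)
  else integer(0)
  groups <- data.frame(segment_id = rep(segments$segment_id, N),
                       group_size = sizes)
  list(N = as.integer(N), tau = tau, occupied = occupied, X = X,
       lambda = lambda, groups = groups)
}

#' Simulate detections of latent groups
#'
#' Each latent group receives a perpendicular distance
#' `y ~ Uniform(0, W)` and is retained with the half-normal probability
#' `exp(-y^2 / (2 sigma_i^2))`, where `sigma_i = exp(Y_i alpha)` uses the
#' segment's binary sea-condition covariates.
#'
#' @param counts Result of [simulate_counts()].
#' @param segments Segment table with `segment_id, wave_bin, wind_bin,
#'   sea_bin`.
#' @param config A [sim_config].
#' @return List: `sightings` (data frame `sighting_id, segment_id,
#'   species, perp_dist_km, group_size`) and `n` (observed group count per
#'   segment, aligned with `segments`).
#' @export
simulate_detections <- function(counts, segments, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  W <- config$truncation_W
  groups <- counts$groups
  Y <- as.matrix(cbind(1, segments[, c("wave_bin", "wind_bin", "sea_bin")]))
  sigma_seg <- sigma_for(Y, config$true_alpha)
  idx <- match(groups$segment_id, segments$segment_id)
  if (nrow(groups) > 0) {
    y <- stats::runif(nrow(groups), 0, W)
    keep <- stats::runif(nrow(groups)) < exp(-y^2 / (2 * sigma_seg[idx]^2))
  } else {
    y <- numeric(0); keep <- logical(0)
  }
  sightings <- data.frame(
    sighting_id = seq_len(sum(keep)),
    segment_id = groups$segment_id[keep],
    species = rep("synthetic", sum(keep)),
    perp_dist_km = y[keep],
    group_size = groups$group_size[keep])
  n <- tabulate(match(sightings$segment_id, segments$segment_id),
                nbins = nrow(segments))
  list(sightings = sightings, n = as.integer(n))
}

#' Simulate daily vessel tracking pings
#'
#' Vessels are based at ports and emit one or more daily positions
#' clustered around a day-specific excursion centre; whole days are
#' occasionally dropped to emulate tracking-feed gaps.
#'
#' @param config A [sim_config].
#' @param fleets Fleet labels to sample vessels from.
#' @param gap_prob Probability a calendar day is missing from the feed.
#' @param activity_prob Probability a vessel is at sea on an available
#'   day.
#' @param excursion_sd SD (km) of daily excursion centres around the home
#'   port.
#' @return Data frame: `vessel_id, fleet, date, x, y`.
#' @export
simulate_vessel_tracks <- function(config,
                                   fleets = c("artisanal", "industrial"),
                                   gap_prob = 0.05,
                                   activity_prob = 0.8,
                                   excursion_sd = 12) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_vessels <= 0 || config$n_days <= 0)
    stop_("invalid configuration: n_vessels and n_days must be positive")
  set.seed(config$seed + 5L)
  ext <- config$grid_extent
  ports <- config$ports
  if (any(ports$x < 0 | ports$x > ext[1] | ports$y < 0 | ports$y > ext[2]))
    stop_("invalid configuration: ports must lie inside the grid")
  home <- sample(nrow(ports), config$n_vessels, replace = TRUE)
  fleet <- sample(fleets, config$n_vessels, replace = TRUE)
  dates <- as.Date("2019-01-01") + seq_len(config$n_days) - 1L
  dates <- dates[stats::runif(length(dates)) >= gap_prob]
  rows <- list()
  for (d in seq_along(dates)) {
    at_sea <- which(stats::runif(config$n_vessels) < activity_prob)
    for (v in at_sea) {
      centre <- c(ports$x[home[v]], ports$y[home[v]]) +
        stats::rnorm(2, 0, excursion_sd)
      np <- 1L + stats::rpois(1, 2)
      rows[[length(rows) + 1L]] <- data.frame(
        vessel_id = v, fleet = fleet[v], date = dates[d],
        x = pmin(pmax(centre[1] + stats::rnorm(np, 0, 3), 0), ext[1] - 1e-9),
        y = pmin(pmax(centre[2] + stats::rnorm(np, 0, 3), 0), ext[2] - 1e-9))
    }
  }
  do.call(rbind, rows)
}

#' Generate a complete synthetic survey
#'
#' Runs the full generative chain: environment fields, tracklines,
#' segmentation, observational-covariate binarization, covariate
#' extraction, latent counts, and detections.  The returned `truth`
#' element records every generative parameter, including the realized
#' total number of individuals on the grid's expected surface.
#'
#' @param config A [sim_config].
#' @param constant_fields Passed to [simulate_environment()].
#' @return List of class `synthetic_survey`: `config`, `grid`,
#'   `tracklines`, `segments` (analysis table with covariates, binary
#'   condition flags and observed counts `n`), `sightings`, `counts`
#'   (latent structures) and `truth`.
#' @export
simulate_survey <- function(config = sim_config(),
                            constant_fields = character()) {
  grid <- simulate_environment(config, constant = constant_fields)
  tracks <- simulate_tracklines(config)
  segments <- segment_effort(tracks, config$target_segment_length)
  bins <- binarize_observational(segments$wave_m, segments$wind_kn,
                                 segments$sea_beaufort)
  segments <- cbind(segments, bins)
  counts <- simulate_counts(config, segments, grid)
  segments <- cbind(segments, as.data.frame(counts$X))
  det <- simulate_detections(counts, segments, config)
  segments$n <- det$n
  truth <- list(
    beta0 = config$true_beta0, beta = as.list(config$true_beta),
    psi = config$true_psi, alpha = config$true_alpha,
    sigma_tau = config$sigma_tau, W = config$truncation_W,
    group_size_mean = config$group_size_mean,
    group_size_dispersion = config$group_size_dispersion,
    n_segments = nrow(segments), total_latent_groups = sum(counts$N),
    expected_density_truth = mean(config$true_psi *
                                    exp(config$true_beta0 +
                                          drop(grid$covariates %*%
                                                 config$true_beta))))
  structure(list(config = config, grid = grid, tracklines = tracks,
                 segments = segments, sightings = det$sightings,
                 counts = counts, truth = truth),
            class = "synthetic_survey")
}

#' Write a synthetic survey to plain-text files
#'
#' Emits the exchange formats the preparation stage reads back: effort
#' CSV, sightings CSV, long-format covariate grid CSV, vessel CSV and a
#' JSON file of all generative parameters.
#'
#' @param survey A `synthetic_survey` from [simulate_survey()].
#' @param dir Output directory (created if needed).
#' @param vessels Optional vessel table from [simulate_vessel_tracks()].
#' @return Invisibly, the named vector of file paths written.
#' @export
write_survey <- function(survey, dir, vessels = NULL) {
  stopifnot(inherits(survey, "synthetic_survey"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    effort = file.path(dir, "effort.csv"),
    sightings = file.path(dir, "sightings.csv"),
    covariates = file.path(dir, "covariates.csv"),
    truth = file.path(dir, "truth.json"))
  eff_cols <- c("segment_id", "x_mid", "y_mid", "length_km", "date",
                "wave_bin", "wind_bin", "sea_bin", "n")
  utils::write.csv(survey$segments[, eff_cols], paths["effort"],
                   row.names = FALSE)
  utils::write.csv(survey$sightings, paths["sightings"], row.names = FALSE)
  write_grid_csv(survey$grid, paths["covariates"])
  jsonlite::write_json(survey$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(vessels)) {
    paths["vessels"] <- file.path(dir, "vessels.csv")
    utils::write.csv(vessels, paths["vessels"], row.names = FALSE)
  }
  invisible(paths)
}
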