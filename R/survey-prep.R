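# Survey preparation: from raw tracklines and sightings to the analysis
# table the count model consumes.

# Interpolated point at along-track distance s (km) from the track start.
point_along <- function(x, y, cum, s) {
  j <- findInterval(s, cum, rightmost.closed = TRUE)
  j <- min(max(j, 1L), length(cum) - 1L)
  f <- (s - cum[j]) / max(cum[j + 1L] - cum[j], 1e-12)
  c(x[j] + f * (x[j + 1L] - x[j]), y[j] + f * (y[j + 1L] - y[j]))
}

#' Cut effort tracklines into contiguous sampling segments
#'
#' Each trackline is divided into consecutive segments of exactly
#' `target_length_km` plus one remainder segment in
#' `(0, target_length_km]`; the segment midpoint is the along-track point
#' at half the segment's length.  Segment lengths re-concatenate to the
#' trackline length exactly.  Columns that are constant within a trackline
#' (date, recorded sea conditions, ...) are carried onto its segments.
#'
#' @param tracklines Data frame of ordered vertices with columns
#'   `track_id, x, y` (km) and any per-track constant columns.
#' @param target_length_km Cut length, km (default 10).
#' @return Data frame of segments: `segment_id, track_id, x_mid, y_mid,
#'   length_km` plus carried columns.  Degenerate (zero-length) tracklines
#'   are skipped with a warning.
#' @export
segment_effort <- function(tracklines, target_length_km = 10) {
  check_number(target_length_km, "target_length_km", lower = 0,
               strict = TRUE)
  need <- c("track_id", "x", "y")
  if (!all(need %in% names(tracklines)))
    stop_("tracklines need columns track_id, x, y")
  carry <- setdiff(names(tracklines), need)
  out <- list()
  for (tid in unique(tracklines$track_id)) {
    tr <- tracklines[tracklines$track_id == tid, , drop = FALSE]
    if (nrow(tr) < 2L) {
      warning("trackline ", tid, " has fewer than 2 points; skipped")
      next
    }
    cum <- c(0, cumsum(sqrt(diff(tr$x)^2 + diff(tr$y)^2)))
    total <- cum[length(cum)]
    if (total <= 0) {
      warning("trackline ", tid, " has zero length; skipped")
      next
    }
    starts <- seq(0, total, by = target_length_km)
    if (abs(starts[length(starts)] - total) < 1e-9)
      starts <- starts[-length(starts)]
    ends <- pmin(starts + target_length_km, total)
    mid_s <- (starts + ends) / 2
    mids <- t(vapply(mid_s, function(s)
      point_along(tr$x, tr$y, cum, s), numeric(2)))
    seg <- data.frame(track_id = tid, x_mid = mids[, 1], y_mid = mids[, 2],
                      length_km = ends - starts)
    for (cc in carry) seg[[cc]] <- tr[[cc]][1L]
    out[[length(out) + 1L]] <- seg
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res <- cbind(segment_id = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

#' Binarize raw observational covariates
#'
#' Sea-condition covariates enter the detection model as binary flags: a
#' value at or below its cutoff codes 0 (good conditions), above codes 1.
#' Default cutoffs sit at the midpoints of the operational threshold
#' ranges (wave 1.75-2.25 m, wind 17-21 kn) and at Beaufort 2 for sea
#' state.  Effort stops at Beaufort 4, so such records are flagged
#' off-effort rather than binarized.
#'
#' @param wave_m Wave height, metres.
#' @param wind_kn Wind speed, knots.
#' @param sea_beaufort Sea state, Beaufort scale.
#' @param wave_cut,wind_cut,sea_cut Scalar cutoffs; `wave_cut` must lie in
#'   `[1.75, 2.25]`, `wind_cut` in `[17, 21]`, `sea_cut` is 2.
#' @return Data frame `wave_bin, wind_bin, sea_bin` (integer 0/1) and
#'   `off_effort` (`TRUE` where `sea_beaufort >= 4`).
#' @export
binarize_observational <- function(wave_m, wind_kn, sea_beaufort,
                                   wave_cut = 2, wind_cut = 19,
                                   sea_cut = 2) {
  check_number(wave_cut, "wave_cut", lower = 1.75, upper = 2.25)
  check_number(wind_cut, "wind_cut", lower = 17, upper = 21)
  check_number(sea_cut, "sea_cut", lower = 2, upper = 2)
  if (any(wave_m < 0 | wind_kn < 0 | sea_beaufort < 0, na.rm = TRUE))
    stop_("raw observational covariates must be non-negative")
  data.frame(
    wave_bin = as.integer(wave_m > wave_cut),
    wind_bin = as.integer(wind_kn > wind_cut),
    sea_bin = as.integer(sea_beaufort > sea_cut),
    off_effort = sea_beaufort >= 4)
}

#' Extract covariate values at segment midpoints
#'
#' The value of the raster cell containing each midpoint is used (no
#' interpolation).  A midpoint falling outside the grid or on a missing
#' value is a hard error naming the segment.
#'
#' @param segments Data frame with `segment_id, x_mid, y_mid`.
#' @param grid A [cov_grid] with covariates.
#' @param covariates Covariate names to extract (default: all).
#' @return Numeric matrix, one row per segment.
#' @export
extract_covariates <- function(segments, grid,
                               covariates = colnames(grid$covariates)) {
  stopifnot(inherits(grid, "cov_grid"))
  if (is.null(grid$covariates)) stop_("grid carries no covariates")
  missing_cov <- setdiff(covariates, colnames(grid$covariates))
  if (length(missing_cov))
    stop_("covariate(s) missing from grid: ",
          paste(missing_cov, collapse = ", "))
  cells <- cell_at(grid, segments$x_mid, segments$y_mid)
  X <- grid$covariates[cells, covariates, drop = FALSE]
  bad <- !stats::complete.cases(X) | is.na(cells)
  if (any(bad))
    stop_("no covariate value at midpoint of segment(s): ",
          paste(segments$segment_id[bad], collapse = ", "))
  X
}

#' Truncate sightings and build per-species analysis tables
#'
#' Sightings beyond the species' truncation distance `W` are dropped;
#' the observed count `n` per segment is the number of retained sightings.
#' Species with fewer than `min_sightings` retained sightings are flagged
#' as excluded from modelling (their tables are still returned: zero
#' counts are data).
#'
#' @param sightings Data frame with `segment_id, species, perp_dist_km`.
#' @param segments Segment table with `segment_id`.
#' @param W_by_species Named vector of truncation distances (km).
#' @param min_sightings Minimum retained sightings required for modelling
#'   (default 30).
#' @return Named list per species: `segments` (with column `n`),
#'   `sightings` (retained), `W`, `n_used`, `included`.
#' @export
truncate_and_count <- function(sightings, segments, W_by_species,
                               min_sightings = 30) {
  if (any(sightings$perp_dist_km < 0))
    stop_("negative perpendicular distance in sightings")
  if (is.null(names(W_by_species)))
    stop_("'W_by_species' must be a named vector")
  if (any(W_by_species <= 0)) stop_("truncation distances must be > 0")
  unknown <- !(sightings$segment_id %in% segments$segment_id)
  if (any(unknown))
    stop_("sighting(s) reference unknown segment(s): ",
          paste(unique(sightings$segment_id[unknown]), collapse = ", "))
  out <- list()
  for (sp in names(W_by_species)) {
    W <- W_by_species[[sp]]
    keep <- sightings[sightings$species == sp &
                        sightings$perp_dist_km <= W, , drop = FALSE]
    seg <- segments
    seg$n <- tabulate(match(keep$segment_id, segments$segment_id),
                      nbins = nrow(segments))
    out[[sp]] <- list(segments = seg, sightings = keep, W = W,
                      n_used = nrow(keep),
                      included = nrow(keep) >= min_sightings)
  }
  out
}

#' Centre and scale environmental covariates
#'
#' Each column is standardized to mean 0, sd 1; the constants are stored
#' for reuse on prediction grids (never re-estimated there), and the
#' Pearson correlation matrix is returned for collinearity screening.
#'
#' @param X Numeric matrix or data frame of covariates (>= 2 rows).
#' @return List: `X` (standardized matrix), `center`, `scale`,
#'   `correlation`.
#' @export
standardize_covariates <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop_("need at least 2 rows to standardize")
  if (any(!is.finite(X))) stop_("covariates must be finite")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop_("zero-variance covariate(s): ",
          paste(colnames(X)[sds == 0], collapse = ", "))
  ctr <- colMeans(X)
  Xs <- sweep(sweep(X, 2L, ctr), 2L, sds, "/")
  list(X = Xs, center = ctr, scale = sds, correlation = stats::cor(X))
}

#' Summarize a survey: segments, effort and used sightings
#'
#' Reproduces the headline bookkeeping of a line-transect survey from its
#' raw inputs: number of sampling segments, total on-effort kilometres,
#' and per-species sighting counts after distance truncation, optionally
#' excluding records before a cutoff date (early cruises run under a
#' different observer protocol).
#'
#' @param tracklines Raw trackline vertices (see [segment_effort()]).
#' @param sightings Sightings with `species, perp_dist_km` and, if
#'   `exclude_before` is used, `date`.
#' @param W_by_species Named truncation distances, km.
#' @param target_length_km Segment cut length, km.
#' @param exclude_before Optional `Date`; tracklines/sightings dated
#'   earlier are discarded (requires `date` columns).
#' @return List: `n_segments`, `total_km`, `used_sightings` (named
#'   vector).
#' @export
tabulate_survey <- function(tracklines, sightings, W_by_species,
                            target_length_km = 10, exclude_before = NULL) {
  if (!is.null(exclude_before)) {
    tracklines <- tracklines[as.Date(tracklines$date) >= exclude_before, ,
                             drop = FALSE]
    if ("date" %in% names(sightings))
      sightings <- sightings[as.Date(sightings$date) >= exclude_before, ,
                             drop = FALSE]
  }
  segs <- segment_effort(tracklines, target_length_km)
  used <- vapply(names(W_by_species), function(sp)
    sum(sightings$species == sp &
          sightings$perp_dist_km <= W_by_species[[sp]]), integer(1))
  list(n_segments = nrow(segs), total_km = sum(segs$length_km),
       used_sightings = used)
}
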