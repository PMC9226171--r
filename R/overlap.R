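# Vessel-density gridding and the encounter-risk layer.

#' Vessel density per grid cell from daily tracking pings
#'
#' For each calendar month, the daily number of distinct vessels with at
#' least one recorded position inside a cell is summed and divided by the
#' number of days with any data in that month; monthly layers are then
#' averaged into one.  A vessel pinging several times in the same cell on
#' the same day counts once; no trajectory interpolation between pings is
#' attempted.  Cells never visited get 0 (absence of pings is
#' information in tracking data).
#'
#' @param pings Data frame `vessel_id, date, x, y` and optionally
#'   `fleet`.
#' @param grid A [cov_grid].
#' @param months Optional character vector of months (`"YYYY-MM"`) to
#'   include.
#' @param day_range Accepted range of days-with-data per month; months
#'   outside it are kept with a warning (tracking feeds normally cover
#'   25-31 days).
#' @return If `pings` has a `fleet` column, a named list of per-fleet
#'   density vectors (one value per grid cell, vessels/day); otherwise a
#'   single vector.  Each vector carries a `months` attribute.
#' @export
vessel_density <- function(pings, grid, months = NULL,
                           day_range = c(25, 31)) {
  stopifnot(inherits(grid, "cov_grid"))
  need <- c("vessel_id", "date", "x", "y")
  miss <- setdiff(need, names(pings))
  if (length(miss))
    stop_("pings lack column(s): ", paste(miss, collapse = ", "))
  if ("fleet" %in% names(pings)) {
    fleets <- sort(unique(pings$fleet))
    out <- lapply(fleets, function(fl)
      vessel_density(pings[pings$fleet == fl,
                           setdiff(names(pings), "fleet"), drop = FALSE],
                     grid, months, day_range))
    names(out) <- fleets
    return(out)
  }
  cell <- cell_at(grid, pings$x, pings$y)
  keep <- !is.na(cell)
  pings <- pings[keep, , drop = FALSE]
  cell <- cell[keep]
  month <- format(as.Date(pings$date), "%Y-%m")
  if (!is.null(months)) {
    sel <- month %in% months
    pings <- pings[sel, , drop = FALSE]
    cell <- cell[sel]; month <- month[sel]
  }
  if (!nrow(pings)) stop_("no pings left after filtering")
  ncell <- grid$nx * grid$ny
  layers <- list()
  for (m in sort(unique(month))) {
    inm <- month == m
    days <- length(unique(pings$date[inm]))
    if (days < day_range[1] || days > day_range[2])
      warning(sprintf("month %s has %d day(s) with data (expected %d-%d)",
                      m, days, day_range[1], day_range[2]))
    trip <- unique(data.frame(v = pings$vessel_id[inm],
                              d = as.character(pings$date[inm]),
                              cell = cell[inm]))
    layers[[m]] <- tabulate(trip$cell, nbins = ncell) / days
  }
  vd <- Reduce(`+`, layers) / length(layers)
  attr(vd, "months") <- names(layers)
  vd
}

#' Relative probability of cetacean-vessel encounter
#'
#' `Pw_i = N_i / sum(N)` is the relative probability of a cetacean being
#' in cell i, `Pv_i = VD_i / sum(VD)` the relative vessel presence, and
#' `RPCVE_i = Pw_i Pv_i / sum_j(Pw_j Pv_j)` the normalized product: a
#' relative encounter-risk surface summing to 1.
#'
#' @param N_grid Predicted cetacean density layer (per cell, >= 0).
#' @param VD_grid Vessel-density layer on the same grid.
#' @return List: `Pw`, `Pv`, `RPCVE` (each summing to 1).
#' @export
rpcve <- function(N_grid, VD_grid) {
  if (length(N_grid) != length(VD_grid))
    stop_("layers must be on the same grid")
  if (any(N_grid < 0 | VD_grid < 0, na.rm = TRUE))
    stop_("layers must be non-negative")
  if (sum(N_grid) <= 0 || sum(VD_grid) <= 0)
    stop_("all-zero layer: normalization undefined")
  Pw <- N_grid / sum(N_grid)
  Pv <- VD_grid / sum(VD_grid)
  prod <- Pw * Pv
  if (sum(prod) <= 0)
    stop_("layers have disjoint support: encounter probability degenerate")
  list(Pw = Pw, Pv = Pv, RPCVE = prod / sum(prod))
}

#' Schoener's D and Warren's I niche-overlap statistics
#'
#' Both layers are min-max rescaled to `[0, 1]` (the convention of the
#' niche-overlap literature) and normalized to probability vectors `p`,
#' `q`; then `D = 1 - sum(|p - q|)/2` and
#' `I = 1 - sum((sqrt(p) - sqrt(q))^2)/2`.  Both lie in `[0, 1]`: 0 for
#' disjoint distributions, 1 iff the layers are proportional after
#' rescaling.
#'
#' @param x,y Non-negative layers on the same grid.
#' @param rescale `"minmax"` (default) rescales each layer to `[0, 1]`
#'   first and errors on constant layers (rescale undefined); `"none"`
#'   treats the inputs as already-comparable intensity layers.
#' @return Named vector `c(D = ..., I = ...)`.
#' @export
overlap_stats <- function(x, y, rescale = c("minmax", "none")) {
  rescale <- match.arg(rescale)
  if (length(x) != length(y)) stop_("layers must be on the same grid")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_("layers must be finite")
  if (rescale == "minmax") {
    mm <- function(v) {
      r <- range(v)
      if (r[1] == r[2])
        stop_("constant layer: min-max rescale undefined")
      (v - r[1]) / (r[2] - r[1])
    }
    x <- mm(x); y <- mm(y)
  }
  if (any(x < 0) || any(y < 0)) stop_("layers must be non-negative")
  if (sum(x) <= 0 || sum(y) <= 0) stop_("all-zero layer")
  p <- x / sum(x)
  q <- y / sum(y)
  c(D = 1 - sum(abs(p - q)) / 2,
    I = 1 - sum((sqrt(p) - sqrt(q))^2) / 2)
}
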