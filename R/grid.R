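#' Planar covariate grid
#'
#' A regular square-celled grid on a planar km coordinate system with the
#' origin at the lower-left corner.  Cell `(r, c)` (row-major, 1-based)
#' covers the half-open square `[ (c-1)s, cs ) x [ (r-1)s, rs )` in
#' `(x, y)`, with `s` the cell size in km.  Covariate values are stored as
#' a cells-by-covariates matrix in row-major cell order.  Real-world
#' longitude/latitude data are expected to be projected to planar km before
#' entering the grid (a projection shim, not geodesy, is this object's
#' contract).
#'
#' @param nx,ny Number of cells along x and y.
#' @param cell_size Cell edge length in km (default 7, giving 49 km2 cells).
#' @param covariates Optional numeric matrix (`nx * ny` rows) or named list
#'   of per-cell vectors.
#' @return An object of class `cov_grid`.
#' @export
cov_grid <- function(nx, ny, cell_size = 7, covariates = NULL) {
  check_number(nx, "nx", lower = 1)
  check_number(ny, "ny", lower = 1)
  check_number(cell_size, "cell_size", lower = 0, strict = TRUE)
  nx <- as.integer(nx); ny <- as.integer(ny)
  ncell <- nx * ny
  if (!is.null(covariates)) {
    if (is.list(covariates) && !is.matrix(covariates))
      covariates <- do.call(cbind, covariates)
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != ncell)
      stop_("covariate matrix must have nx * ny = ", ncell, " rows")
    if (is.null(colnames(covariates)))
      stop_("covariates must be named")
  }
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  structure(list(
    nx = nx, ny = ny, cell_size = cell_size,
    x = (ix - 0.5) * cell_size,
    y = (iy - 0.5) * cell_size,
    area = rep(cell_size^2, ncell),
    covariates = covariates
  ), class = "cov_grid")
}

#' @export
print.cov_grid <- function(x, ...) {
  cat(sprintf("cov_grid: %d x %d cells of %g km (%g x %g km extent)\n",
              x$nx, x$ny, x$cell_size, x$nx * x$cell_size,
              x$ny * x$cell_size))
  if (!is.null(x$covariates))
    cat("covariates:", paste(colnames(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' Locate grid cells containing points
#'
#' @param grid A [cov_grid].
#' @param x,y Point coordinates in km.
#' @return Integer cell indices (row-major); `NA` for points outside the
#'   grid.
#' @export
cell_at <- function(grid, x, y) {
  stopifnot(inherits(grid, "cov_grid"))
  ix <- floor(x / grid$cell_size) + 1
  iy <- floor(y / grid$cell_size) + 1
  out <- (iy - 1) * grid$nx + ix
  bad <- ix < 1 | ix > grid$nx | iy < 1 | iy > grid$ny |
    !is.finite(x) | !is.finite(y)
  out[bad] <- NA_integer_
  as.integer(out)
}

#' @export
as.data.frame.cov_grid <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
  df <- data.frame(cell_id = seq_along(x$x), x = x$x, y = x$y,
                   area = x$area)
  if (!is.null(x$covariates)) df <- cbind(df, as.data.frame(x$covariates))
  df
}

#' Read/write a gridded covariate layer as long-format CSV
#'
#' Plain-text exchange format for covariate and density layers: one row per
#' cell with `x`, `y` (cell centres, km) and one column per layer value.
#'
#' @param grid A [cov_grid].
#' @param path Output CSV path.
#' @return `write_grid_csv` returns `path` invisibly; `read_grid_csv`
#'   returns a `cov_grid`.
#' @export
write_grid_csv <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  df <- utils::read.csv(path)
  xs <- sort(unique(df$x)); ys <- sort(unique(df$y))
  cell_size <- if (length(xs) > 1) diff(xs)[1] else 2 * xs[1]
  grid <- cov_grid(length(xs), length(ys), cell_size)
  ord <- order(match(df$y, ys), match(df$x, xs))
  covs <- setdiff(names(df), c("cell_id", "x", "y", "area"))
  if (length(covs))
    grid$covariates <- as.matrix(df[ord, covs, drop = FALSE])
  grid
}
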