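#' Single-band raster grid
#'
#' The carrier type for every raster layer in the package: digital numbers
#' (DN), radiance in W/(m^2 sr um), dimensionless indices (EVI, HSI, RNAHSI),
#' road-network density (length per unit area) and population (persons per
#' cell). A grid is a numeric matrix plus a north-up, square-cell affine
#' geotransform in a projected CRS whose units are metres. Missing cells are
#' stored as `NA`; the `nodata` field is only the sentinel used on disk.
#'
#' The value of cell `(r, c)` is the sample at the cell centre
#' `x = x0 + (c - 0.5) * cell`, `y = y0 - (r - 0.5) * cell`, where `(x0, y0)`
#' is the upper-left corner of the upper-left cell.
#'
#' @param values numeric matrix (rows = north to south).
#' @param x0,y0 coordinates of the upper-left corner of the grid, metres.
#' @param cell square cell size, metres, > 0.
#' @param crs character identifier of a projected CRS in metres
#'   (e.g. `"EPSG:32650"`). Purely a label: no reprojection is performed.
#' @param nodata sentinel written to / read from disk, or `NULL`.
#' @return An object of class `rn_grid`.
#' @export
rn_grid <- function(values, x0 = 0, y0 = NULL, cell = 100,
                    crs = "local-metres", nodata = -9999) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (!is.numeric(cell) || length(cell) != 1L || !is.finite(cell) || cell <= 0)
    stop("cell size must be a single positive number (metres)", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("grid must have at least one row and one column", call. = FALSE)
  if (is.null(y0)) y0 <- nrow(values) * cell
  bad <- !is.na(values) & !is.finite(values)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at cell (%d, %d); use NA for nodata",
                 idx[1L], idx[2L]), call. = FALSE)
  }
  structure(
    list(values = values, x0 = as.numeric(x0), y0 = as.numeric(y0),
         cell = as.numeric(cell), crs = as.character(crs),
         nodata = if (is.null(nodata)) NULL else as.numeric(nodata)),
    class = "rn_grid")
}

#' Grid geometry without values
#'
#' Shape, geotransform and CRS of an analysis grid — the common 100 m grid
#' every layer is aligned onto before index computation.
#'
#' @param nrow,ncol grid dimensions.
#' @inheritParams rn_grid
#' @return An object of class `rn_grid_spec`.
#' @export
rn_grid_spec <- function(nrow, ncol, x0 = 0, y0 = NULL, cell = 100,
                         crs = "local-metres") {
  if (nrow < 1L || ncol < 1L) stop("grid spec needs nrow, ncol >= 1", call. = FALSE)
  if (cell <= 0) stop("cell size must be positive", call. = FALSE)
  if (is.null(y0)) y0 <- nrow * cell
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 x0 = as.numeric(x0), y0 = as.numeric(y0),
                 cell = as.numeric(cell), crs = as.character(crs)),
            class = "rn_grid_spec")
}

#' @export
print.rn_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<rn_grid> %d x %d cells @ %g m, CRS %s\n",
              nrow(v), ncol(v), x$cell, x$crs))
  cat(sprintf("  origin (%g, %g); %d NA cells\n", x$x0, x$y0, sum(is.na(v))))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  if (all(is.finite(rng))) cat(sprintf("  values in [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
print.rn_grid_spec <- function(x, ...) {
  cat(sprintf("<rn_grid_spec> %d x %d cells @ %g m, CRS %s, origin (%g, %g)\n",
              x$nrow, x$ncol, x$cell, x$crs, x$x0, x$y0))
  invisible(x)
}

is_rn_grid <- function(x) inherits(x, "rn_grid")

#' Extract the geometry of a grid
#' @param grid an [rn_grid].
#' @return The grid's [rn_grid_spec].
#' @export
grid_spec_of <- function(grid) {
  stopifnot(is_rn_grid(grid))
  rn_grid_spec(nrow(grid$values), ncol(grid$values),
               grid$x0, grid$y0, grid$cell, grid$crs)
}

#' Make a grid from a spec and values
#' @param spec an [rn_grid_spec].
#' @param values matrix of matching shape, or a single number to fill with.
#' @param nodata disk sentinel.
#' @return An [rn_grid].
#' @export
grid_from_spec <- function(spec, values = 0, nodata = -9999) {
  stopifnot(inherits(spec, "rn_grid_spec"))
  if (length(values) == 1L)
    values <- matrix(values, spec$nrow, spec$ncol)
  if (!identical(dim(values), c(spec$nrow, spec$ncol)))
    stop("values shape does not match spec", call. = FALSE)
  rn_grid(values, spec$x0, spec$y0, spec$cell, spec$crs, nodata)
}

spec_equal <- function(a, b, tol = 1e-6) {
  a$nrow == b$nrow && a$ncol == b$ncol &&
    abs(a$x0 - b$x0) < tol && abs(a$y0 - b$y0) < tol &&
    abs(a$cell - b$cell) < tol && identical(a$crs, b$crs)
}

#' Are two grids aligned?
#'
#' Aligned means identical shape, geotransform and CRS — the precondition for
#' any cell-wise algebra between layers.
#' @param a,b [rn_grid] objects.
#' @return Logical.
#' @export
grids_aligned <- function(a, b) {
  spec_equal(grid_spec_of(a), grid_spec_of(b))
}

# Which attribute differs; "" if aligned. Used for error messages.
alignment_mismatch <- function(a, b) {
  sa <- grid_spec_of(a); sb <- grid_spec_of(b)
  if (sa$nrow != sb$nrow || sa$ncol != sb$ncol) return("shape")
  if (abs(sa$x0 - sb$x0) >= 1e-6 || abs(sa$y0 - sb$y0) >= 1e-6) return("origin")
  if (abs(sa$cell - sb$cell) >= 1e-6) return("cell size")
  if (!identical(sa$crs, sb$crs)) return("crs")
  ""
}

#' Cell-centre coordinates of a grid
#' @param spec an [rn_grid_spec] (or [rn_grid]).
#' @return List with vectors `x` (length ncol) and `y` (length nrow, north to
#'   south), in CRS metres.
#' @export
cell_centres <- function(spec) {
  if (is_rn_grid(spec)) spec <- grid_spec_of(spec)
  list(x = spec$x0 + (seq_len(spec$ncol) - 0.5) * spec$cell,
       y = spec$y0 - (seq_len(spec$nrow) - 0.5) * spec$cell)
}

#' Cell area in square kilometres
#' @param grid an [rn_grid] or [rn_grid_spec].
#' @return Single number, km^2.
#' @export
cell_area_km2 <- function(grid) {
  cell <- if (is_rn_grid(grid)) grid$cell else grid$cell
  (cell / 1000)^2
}
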