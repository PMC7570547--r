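#' Read a raster from an ESRI ASCII grid file
#'
#' The on-disk raster format of the package is the plain-text ESRI ASCII grid
#' (`.asc`), readable by GDAL, QGIS and ArcGIS. The CRS is carried in a
#' sidecar file `<path>.prj` (free-text identifier, e.g. `EPSG:32650`); a
#' missing sidecar yields CRS `"local-metres"` with a message. The CRS must
#' be projected in metres — geographic rasters must be reprojected upstream.
#'
#' @param path path to a `.asc` file.
#' @return An [rn_grid]; the file's `NODATA_value` cells become `NA`.
#' @export
read_grid_asc <- function(path) {
  if (!file.exists(path)) stop("no such raster file: ", path, call. = FALSE)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1L])) {
      hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
      n_hdr <- n_hdr + 1L
    } else break
  }
  req <- c("ncols", "nrows", "cellsize")
  if (!all(req %in% names(hdr)))
    stop("not an ESRI ASCII grid (missing ncols/nrows/cellsize header): ",
         path, call. = FALSE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (!is.null(hdr$xllcorner)) {
    x0 <- hdr$xllcorner
    y0 <- hdr$yllcorner + nr * hdr$cellsize
  } else if (!is.null(hdr$xllcenter)) {
    x0 <- hdr$xllcenter - hdr$cellsize / 2
    y0 <- hdr$yllcenter - hdr$cellsize / 2 + nr * hdr$cellsize
  } else stop("ESRI ASCII grid lacks corner/center coordinates: ", path,
              call. = FALSE)
  vals <- scan(path, what = numeric(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("raster %s: expected %d values, found %d",
                 path, nr * nc, length(vals)), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- hdr$nodata_value
  if (!is.null(nodata)) m[m == nodata] <- NA_real_
  prj <- paste0(path, ".prj")
  crs <- if (file.exists(prj)) trimws(readLines(prj, n = 1L)) else {
    message("no .prj sidecar for ", path, "; assuming local metric CRS")
    "local-metres"
  }
  if (grepl("4326|longlat|degree", crs, ignore.case = TRUE))
    stop("raster CRS '", crs, "' looks geographic; reproject to a metric ",
         "projected CRS (e.g. UTM) before use", call. = FALSE)
  rn_grid(m, x0, y0, hdr$cellsize, crs,
          nodata = if (is.null(nodata)) -9999 else nodata)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' `NA` cells are written as the grid's `nodata` sentinel; the CRS goes to a
#' `<path>.prj` sidecar. Values are written with full double precision so a
#' round trip is lossless to within text formatting (~15 significant digits).
#'
#' @param grid an [rn_grid].
#' @param path output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_grid_asc <- function(grid, path) {
  stopifnot(is_rn_grid(grid))
  v <- grid$values
  nodata <- if (is.null(grid$nodata)) -9999 else grid$nodata
  if (any(v == nodata, na.rm = TRUE))
    stop("grid contains the nodata sentinel ", nodata,
         " as a real value; choose another sentinel", call. = FALSE)
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$x0),
    sprintf("yllcorner %.10g", grid$y0 - nrow(v) * grid$cell),
    sprintf("cellsize %.10g", grid$cell),
    sprintf("NODATA_value %.10g", nodata))
  body <- apply(v, 1L, function(row) paste(format(row, digits = 15,
                                                  trim = TRUE,
                                                  scientific = TRUE),
                                           collapse = " "))
  writeLines(c(hdr, body), path)
  writeLines(grid$crs, paste0(path, ".prj"))
  invisible(path)
}
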