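#' Census zone set
#'
#' Polygonal census zones (townships) with integer population counts. Each
#' zone is one or more rings in CRS metres; the first ring of a polygon is
#' the outer boundary, further rings are holes (even-odd rule).
#'
#' @param zone_id unique zone identifiers (coerced to character).
#' @param polygons list (one entry per zone) of lists of rings; each ring an
#'   `n x 2` coordinate matrix (closed or open — closing is implied).
#' @param population non-negative integer counts, one per zone (may be `NA`
#'   before the census join).
#' @param area_km2 optional zone areas; computed from the rings (shoelace,
#'   holes subtracted) when omitted.
#' @param crs projected CRS label.
#' @return Object of class `zone_set`.
#' @export
zone_set <- function(zone_id, polygons, population = NULL, area_km2 = NULL,
                     crs = "local-metres") {
  zone_id <- as.character(zone_id)
  if (anyDuplicated(zone_id)) stop("zone_id values must be unique", call. = FALSE)
  if (length(polygons) != length(zone_id))
    stop("one polygon (ring list) per zone required", call. = FALSE)
  polygons <- lapply(polygons, function(p) {
    if (is.matrix(p)) p <- list(p)
    lapply(p, function(ring) {
      ring <- as.matrix(ring)
      if (ncol(ring) != 2L || nrow(ring) < 3L)
        stop("each ring must be an n x 2 matrix with n >= 3", call. = FALSE)
      if (!all(is.finite(ring))) stop("non-finite ring coordinates", call. = FALSE)
      ring
    })
  })
  if (is.null(population)) population <- rep(NA_integer_, length(zone_id))
  if (length(population) != length(zone_id))
    stop("one population count per zone required", call. = FALSE)
  if (any(!is.na(population) & population < 0))
    stop("populations must be non-negative", call. = FALSE)
  if (is.null(area_km2))
    area_km2 <- vapply(polygons, polygon_area_km2, numeric(1))
  if (any(area_km2 <= 0)) stop("zone areas must be positive", call. = FALSE)
  structure(list(zone_id = zone_id, polygons = polygons,
                 population = as.numeric(population),
                 area_km2 = as.numeric(area_km2), crs = crs),
            class = "zone_set")
}

#' @export
print.zone_set <- function(x, ...) {
  cat(sprintf("<zone_set> %d zones, %.1f km^2 total, CRS %s\n",
              length(x$zone_id), sum(x$area_km2), x$crs))
  if (!all(is.na(x$population)))
    cat(sprintf("  population total %s\n",
                format(sum(x$population, na.rm = TRUE), big.mark = ",")))
  invisible(x)
}

#' Number of zones
#' @param zones a [zone_set].
#' @return Integer count.
#' @export
n_zones <- function(zones) length(zones$zone_id)

# shoelace area of a ring list: |outer| - sum |holes|, in km^2
polygon_area_km2 <- function(rings) {
  area_m2 <- function(ring) {
    x <- ring[, 1L]; y <- ring[, 2L]
    n <- length(x)
    abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
  }
  a <- vapply(rings, area_m2, numeric(1))
  (a[1L] - sum(a[-1L])) / 1e6
}

# rings -> NA-separated boundary matrix for mgcv::in.out
rings_to_bnd <- function(rings) {
  closed <- lapply(rings, function(r) {
    if (!all(r[1L, ] == r[nrow(r), ])) r <- rbind(r, r[1L, ])
    r
  })
  do.call(rbind, lapply(seq_along(closed), function(i) {
    if (i == 1L) closed[[i]] else rbind(c(NA, NA), closed[[i]])
  }))
}

#' Assign grid cells to zones by cell-centre containment
#'
#' Each cell belongs to the zone whose polygon contains its centre; cells
#' outside every zone get 0. Where zones overlap or a centre lies on a shared
#' boundary, the first zone in `zone_id` order wins (deterministic
#' tie-break). Containment is the even-odd rule (`mgcv::in.out`).
#'
#' @param zones a [zone_set].
#' @param spec [rn_grid_spec] of the analysis grid (same CRS).
#' @return Integer matrix of the grid's shape with zone indices (positions in
#'   `order(zones$zone_id)`-stable original order), 0 = outside all zones.
#' @export
zone_assignment <- function(zones, spec) {
  stopifnot(inherits(zones, "zone_set"))
  if (is_rn_grid(spec)) spec <- grid_spec_of(spec)
  if (!identical(zones$crs, spec$crs))
    stop(sprintf("zone CRS '%s' does not match grid CRS '%s'",
                 zones$crs, spec$crs), call. = FALSE)
  ctr <- cell_centres(spec)
  pts <- cbind(rep(ctr$x, each = spec$nrow), rep(ctr$y, times = spec$ncol))
  assign <- matrix(0L, spec$nrow, spec$ncol)
  ord <- order(zones$zone_id)
  for (zi in ord) {
    bnd <- rings_to_bnd(zones$polygons[[zi]])
    # cheap bounding-box prefilter before the point-in-polygon test
    xr <- range(bnd[, 1L], na.rm = TRUE); yr <- range(bnd[, 2L], na.rm = TRUE)
    cand <- which(assign == 0L &
                    pts[, 1L] >= xr[1L] & pts[, 1L] <= xr[2L] &
                    pts[, 2L] >= yr[1L] & pts[, 2L] <= yr[2L])
    if (!length(cand)) next
    inside <- mgcv::in.out(bnd, pts[cand, , drop = FALSE])
    assign[cand[inside]] <- zi
  }
  assign
}

#' Zonal sum of a raster
#'
#' Sum of non-`NA` cell values over the cells whose centres fall in each
#' zone. Zones containing no cell centre get sum 0 with a warning.
#'
#' @param grid an [rn_grid].
#' @param zones a [zone_set] in the grid's CRS.
#' @param assignment optional precomputed [zone_assignment] matrix (reuse it
#'   when summing many layers over the same zones).
#' @return Named numeric vector, one sum per zone (in `zones` order).
#' @export
zonal_sum <- function(grid, zones, assignment = NULL) {
  stopifnot(is_rn_grid(grid), inherits(zones, "zone_set"))
  if (is.null(assignment)) assignment <- zone_assignment(zones, grid_spec_of(grid))
  v <- grid$values
  v[is.na(v)] <- 0
  nz <- n_zones(zones)
  sums <- vapply(split(as.vector(v), factor(as.vector(assignment),
                                            levels = 0:nz)),
                 sum, numeric(1))[-1L]  # drop the outside-all-zones bin
  names(sums) <- zones$zone_id
  empty <- !(seq_len(nz) %in% assignment)
  if (any(empty))
    warning("zone(s) with no cell centres: ",
            paste(zones$zone_id[empty], collapse = ", "), call. = FALSE)
  sums
}

#' Read census zones from GeoJSON (+ optional census CSV)
#'
#' The GeoJSON must be a FeatureCollection of Polygon / MultiPolygon features
#' with a zone-id property. Populations come either from a `population`
#' property or from a CSV with columns `zone_id, population` joined on id.
#'
#' @param path GeoJSON file.
#' @param census_csv optional CSV path for the population join.
#' @param id_field property holding the zone id (default `"zone_id"`).
#' @param crs CRS label to attach.
#' @return A [zone_set].
#' @export
read_zones_geojson <- function(path, census_csv = NULL, id_field = "zone_id",
                               crs = "local-metres") {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop(path, " is not a GeoJSON FeatureCollection", call. = FALSE)
  ids <- character(); polys <- list(); pops <- numeric()
  ring_to_matrix <- function(ring)
    do.call(rbind, lapply(ring, function(p) c(p[[1L]], p[[2L]])))
  for (ft in gj$features) {
    id <- ft$properties[[id_field]]
    if (is.null(id)) stop("feature without '", id_field, "' property in ",
                          path, call. = FALSE)
    geom <- ft$geometry
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_to_matrix),
      MultiPolygon = {
        # flatten parts; first ring of the first part is "outer", the rest
        # participate via the even-odd rule
        unlist(lapply(geom$coordinates,
                      function(part) lapply(part, ring_to_matrix)),
               recursive = FALSE)
      },
      stop("zone feature with non-polygon geometry '", geom$type, "'",
           call. = FALSE))
    ids <- c(ids, as.character(id))
    polys[[length(polys) + 1L]] <- rings
    p <- ft$properties$population
    pops <- c(pops, if (is.null(p)) NA_real_ else as.numeric(p))
  }
  if (!is.null(census_csv)) {
    cen <- utils::read.csv(census_csv, stringsAsFactors = FALSE)
    if (!all(c("zone_id", "population") %in% names(cen)))
      stop(census_csv, " must have columns zone_id, population", call. = FALSE)
    m <- match(ids, as.character(cen$zone_id))
    if (anyNA(m))
      stop("census CSV is missing zone(s): ",
           paste(ids[is.na(m)], collapse = ", "), call. = FALSE)
    pops <- as.numeric(cen$population[m])
  }
  zone_set(ids, polys, population = pops, crs = crs)
}

#' Write zones to GeoJSON and the census to CSV
#' @param zones a [zone_set].
#' @param path GeoJSON output path.
#' @param census_csv optional CSV output path (`zone_id, population`).
#' @return `path`, invisibly.
#' @export
write_zones_geojson <- function(zones, path, census_csv = NULL) {
  feats <- lapply(seq_len(n_zones(zones)), function(i) {
    rings <- lapply(zones$polygons[[i]], function(r) {
      if (!all(r[1L, ] == r[nrow(r), ])) r <- rbind(r, r[1L, ])
      lapply(seq_len(nrow(r)), function(k) c(r[k, 1L], r[k, 2L]))
    })
    list(type = "Feature",
         properties = list(zone_id = zones$zone_id[[i]],
                           population = zones$population[[i]]),
         geometry = list(type = "Polygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  if (!is.null(census_csv))
    utils::write.csv(data.frame(zone_id = zones$zone_id,
                                population = zones$population),
                     census_csv, row.names = FALSE)
  invisible(path)
}
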