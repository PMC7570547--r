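#' Road classes
#'
#' The six-way functional classification used throughout: expressways, trunk
#' roads, secondary trunk roads, branch roads, railways (incl. subways) and
#' everything else (residential streets, cycle lanes, footpaths).
#' @export
ROAD_CLASSES <- c("expressway", "trunk", "secondary_trunk", "branch",
                  "railway", "other")

#' Classified road network
#'
#' Polylines in a projected metric CRS, each tagged with one of the six road
#' classes. Dual carriageways are assumed merged to centre lines upstream.
#'
#' @param lines list of numeric matrices, each `n x 2` (x, y in metres,
#'   `n >= 2`).
#' @param classes character vector, one class per polyline, each one of
#'   [ROAD_CLASSES].
#' @param crs projected CRS label.
#' @return Object of class `road_network`.
#' @export
road_network <- function(lines, classes, crs = "local-metres") {
  if (!is.list(lines)) stop("`lines` must be a list of coordinate matrices",
                            call. = FALSE)
  if (length(lines) != length(classes))
    stop("one class per polyline required", call. = FALSE)
  classes <- as.character(classes)
  bad_cls <- setdiff(unique(classes), ROAD_CLASSES)
  if (length(bad_cls))
    stop("unknown road class(es): ", paste(bad_cls, collapse = ", "),
         "; valid classes are ", paste(ROAD_CLASSES, collapse = ", "),
         call. = FALSE)
  for (i in seq_along(lines)) {
    m <- lines[[i]]
    if (!is.matrix(m) || ncol(m) != 2L || nrow(m) < 2L)
      stop(sprintf("polyline %d must be an n x 2 matrix with n >= 2", i),
           call. = FALSE)
    if (!all(is.finite(m)))
      stop(sprintf("polyline %d has non-finite coordinates", i), call. = FALSE)
    if (polyline_length(m) <= 0)
      stop(sprintf("polyline %d has zero length", i), call. = FALSE)
  }
  structure(list(lines = lines, classes = classes, crs = crs),
            class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("<road_network> %d polylines, %.1f km total, CRS %s\n",
              length(x$lines), network_length(x) / 1000, x$crs))
  tab <- table(factor(x$classes, levels = ROAD_CLASSES))
  for (cl in names(tab)) if (tab[[cl]] > 0)
    cat(sprintf("  %-16s %d\n", cl, tab[[cl]]))
  invisible(x)
}

polyline_length <- function(m) {
  d <- diff(m)
  sum(sqrt(d[, 1L]^2 + d[, 2L]^2))
}

#' Total length of a road network
#' @param network a [road_network].
#' @param road_class optional single class to restrict to.
#' @return Length in metres.
#' @export
network_length <- function(network, road_class = NULL) {
  keep <- if (is.null(road_class)) seq_along(network$lines)
          else which(network$classes == road_class)
  if (!length(keep)) return(0)
  sum(vapply(network$lines[keep], polyline_length, numeric(1)))
}

# Midpoint discretisation of a polyline into length-weighted sample points.
# Each segment of length L is split into ceiling(L / spacing) equal arcs and
# a point placed at each arc midpoint with weight L / n — the midpoint rule
# along the line, O(spacing^2) accurate for the kernel integral.
densify_polyline <- function(m, spacing) {
  pts <- vector("list", nrow(m) - 1L)
  for (s in seq_len(nrow(m) - 1L)) {
    p0 <- m[s, ]; p1 <- m[s + 1L, ]
    L <- sqrt(sum((p1 - p0)^2))
    if (L == 0) next
    n <- max(1L, as.integer(ceiling(L / spacing)))
    t <- (seq_len(n) - 0.5) / n
    pts[[s]] <- cbind(p0[1L] + t * (p1[1L] - p0[1L]),
                      p0[2L] + t * (p1[2L] - p0[2L]),
                      L / n)
  }
  do.call(rbind, pts)
}

#' Read a classified road network from GeoJSON
#'
#' Accepts a FeatureCollection of LineString / MultiLineString features. The
#' road class is read from `class_field` and mapped through `class_map` (a
#' named character vector tag -> class), so raw OpenStreetMap `highway` /
#' `railway` tags can be translated to the six-way classification.
#'
#' @param path GeoJSON file.
#' @param class_field property holding the class tag (default
#'   `"road_class"`).
#' @param class_map named character vector mapping tag values to
#'   [ROAD_CLASSES]; `NULL` means tags are already class names. Features with
#'   unmapped tags are dropped with a message.
#' @param crs CRS label to attach (GeoJSON itself is CRS-less here).
#' @return A [road_network].
#' @export
read_roads_geojson <- function(path, class_field = "road_class",
                               class_map = NULL, crs = "local-metres") {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop(path, " is not a GeoJSON FeatureCollection", call. = FALSE)
  lines <- list(); classes <- character(); dropped <- 0L
  for (ft in gj$features) {
    tag <- ft$properties[[class_field]]
    cls <- if (is.null(class_map)) tag else unname(class_map[tag])
    if (is.null(cls) || length(cls) != 1L || is.na(cls) ||
        !cls %in% ROAD_CLASSES) { dropped <- dropped + 1L; next }
    geom <- ft$geometry
    coord_sets <- switch(geom$type,
      LineString = list(geom$coordinates),
      MultiLineString = geom$coordinates,
      { dropped <- dropped + 1L; next })
    for (cs in coord_sets) {
      m <- do.call(rbind, lapply(cs, function(p) c(p[[1L]], p[[2L]])))
      lines[[length(lines) + 1L]] <- m
      classes <- c(classes, cls)
    }
  }
  if (dropped > 0L)
    message(dropped, " feature(s) dropped (unmapped class or non-line geometry)")
  road_network(lines, classes, crs)
}

#' Write a road network to GeoJSON
#' @param network a [road_network].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roads_geojson <- function(network, path) {
  feats <- lapply(seq_along(network$lines), function(i) {
    m <- network$lines[[i]]
    list(type = "Feature",
         properties = list(road_class = network$classes[[i]]),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(m)),
                                              function(r) c(m[r, 1L], m[r, 2L]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
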