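#' Parameters for a synthetic city scene
#'
#' Defines the synthetic study conditions: a multi-centre population density
#' surface, roads laid preferentially through high-density areas, a
#' nighttime-light layer tied to density through the radiance calibration
#' with Gaussian "blooming" and multiplicative noise, a 23-scene vegetation
#' stack anti-correlated with density, and a rectangular census partition.
#' Defaults emulate the scale of the real study: a 20 x 20 km city on a
#' 100 m grid, 5 urban centres, 74 census zones (the order of a large
#' city's township count) and a density-vs-road-density exponent of 1.2322.
#'
#' @param grid analysis [rn_grid_spec] (default 200 x 200 cells at 100 m).
#' @param n_centres number of urban centres (default 5).
#' @param centre_scale Gaussian scale of each centre, metres (default 2000).
#' @param road_classes classes to generate (default all of [ROAD_CLASSES]).
#' @param roads_per_class polylines per class (default 6).
#' @param b_true true density ~ RND^b exponent (default 1.2322).
#' @param a_true density scale, persons/km^2 per (m/m^2)^b (default 3.5e7).
#' @param density_floor uniform background density, persons/km^2 (default 0.5)
#'   — keeps every census zone inhabited, as real townships are.
#' @param ntl_blur_sigma Gaussian blooming scale of the NTL layer, metres
#'   (default 260, about two native NTL cells).
#' @param ntl_saturation density (persons/km^2) at which the emitted-light
#'   response is half saturated (default 8000): nighttime light misses part
#'   of the activity over the densest urban fabric, which is precisely the
#'   deficiency the road-network adjustment targets.
#' @param ntl_field_sd log-scale standard deviation of a spatially smooth
#'   multiplicative bias field on the NTL layer (default 0.4), emulating
#'   district-scale differences in lighting per inhabitant.
#' @param ntl_field_scale correlation length of that bias field, metres
#'   (default 2000 — the scale of a city quarter).
#' @param evi_field_sd log-scale standard deviation of the analogous smooth
#'   land-use field on vegetation greenness (default 0.3): the
#'   vegetation-density link in a real city is loosened by parks, bare
#'   ground and construction.
#' @param noise_sd relative (lognormal) noise on the NTL layer (default 0.1).
#' @param n_zones census zones (default 74).
#' @param n_evi vegetation scenes per year (default 23).
#' @param kde_bandwidth bandwidth used for the construction density, metres
#'   (default 3000).
#' @param seed single integer governing all randomness; per-layer sub-streams
#'   are derived from it so layers are independently reproducible.
#' @return Object of class `scene_params`.
#' @export
scene_params <- function(grid = rn_grid_spec(200, 200, cell = 100),
                         n_centres = 5, centre_scale = 2000,
                         road_classes = ROAD_CLASSES, roads_per_class = 6,
                         b_true = 1.2322, a_true = 3.5e7, density_floor = 0.5,
                         ntl_blur_sigma = 260, ntl_saturation = 8000,
                         ntl_field_sd = 0.4, ntl_field_scale = 2000,
                         evi_field_sd = 0.3, noise_sd = 0.1,
                         n_zones = 74, n_evi = 23, kde_bandwidth = 3000,
                         seed = 1L) {
  stopifnot(inherits(grid, "rn_grid_spec"),
            n_centres >= 1, roads_per_class >= 1, n_zones >= 1,
            b_true > 0, noise_sd >= 0, centre_scale > 0, kde_bandwidth > 0,
            all(road_classes %in% ROAD_CLASSES))
  structure(list(grid = grid, n_centres = as.integer(n_centres),
                 centre_scale = centre_scale, road_classes = road_classes,
                 roads_per_class = as.integer(roads_per_class),
                 b_true = b_true, a_true = a_true,
                 density_floor = density_floor,
                 ntl_blur_sigma = ntl_blur_sigma,
                 ntl_saturation = ntl_saturation,
                 ntl_field_sd = ntl_field_sd,
                 ntl_field_scale = ntl_field_scale,
                 evi_field_sd = evi_field_sd, noise_sd = noise_sd,
                 n_zones = as.integer(n_zones), n_evi = as.integer(n_evi),
                 kde_bandwidth = kde_bandwidth, seed = as.integer(seed)),
            class = "scene_params")
}

# deterministic per-layer sub-seed so adding a layer never perturbs others
sub_seed <- function(seed, layer) {
  (as.numeric(seed) * 7919 + 104729 * layer) %% 2147483647
}

# separable Gaussian blur with edge replication; sigma in cells
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur_cols <- function(x) {
    pad <- rbind(x[rep(1L, r), , drop = FALSE], x,
                 x[rep(nrow(x), r), , drop = FALSE])
    f <- stats::filter(pad, k, sides = 2)
    matrix(f[(r + 1):(r + nrow(x)), ], nrow(x), ncol(x))
  }
  t(blur_cols(t(blur_cols(m))))
}

# split `total` cells into k contiguous parts of jittered sizes
partition_sizes <- function(total, k, min_size = 2L) {
  if (total < k * min_size)
    stop("grid too small to hold ", k, " parts of at least ", min_size,
         " cells", call. = FALSE)
  w <- stats::runif(k, 0.7, 1.3)
  sizes <- pmax(min_size, floor(w / sum(w) * total))
  while (sum(sizes) > total) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  while (sum(sizes) < total) sizes[which.min(sizes)] <- sizes[which.min(sizes)] + 1L
  sizes
}

#' Generate a synthetic city scene
#'
#' Builds all pipeline inputs from a single seed: an attractiveness field
#' (mixture of Gaussian centres) steers biased random-walk roads uphill, the
#' true density is a power law in the resulting equal-weight road density
#' (`density = a_true * RND^b_true + floor`), the NTL digital numbers are the
#' inverse radiance calibration of a signal proportional to density —
#' blurred (blooming) and noised — the vegetation stack decays with density,
#' and the census is the per-zone integral of the true density (rounded per
#' zone).
#'
#' @param params a [scene_params].
#' @return Object of class `synthetic_scene`: list with `true_density`
#'   (persons/km^2), `ntl_dn`, `evi_stack` (list of grids), `roads`
#'   ([road_network]), `zones` ([zone_set] with census), `rnd_construction`
#'   (the equal-weight road density the density was built from) and
#'   `params`.
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  spec <- params$grid
  ctr <- cell_centres(spec)
  width <- spec$ncol * spec$cell; height <- spec$nrow * spec$cell
  xmin <- spec$x0; ymax <- spec$y0

  ## 1. urban centres and attractiveness field
  set.seed(sub_seed(params$seed, 1L))
  cx <- xmin + stats::runif(params$n_centres, 0.15, 0.85) * width
  cy <- ymax - stats::runif(params$n_centres, 0.15, 0.85) * height
  amp <- stats::runif(params$n_centres, 0.5, 1)
  xs <- matrix(ctr$x, spec$nrow, spec$ncol, byrow = TRUE)
  ys <- matrix(ctr$y, spec$nrow, spec$ncol)
  attract <- matrix(0, spec$nrow, spec$ncol)
  for (i in seq_len(params$n_centres))
    attract <- attract + amp[i] *
      exp(-((xs - cx[i])^2 + (ys - cy[i])^2) / (2 * params$centre_scale^2))

  ## 2. roads: biased random walks climbing the attractiveness gradient
  set.seed(sub_seed(params$seed, 2L))
  grad <- attract_gradient(attract, spec)
  lines <- list(); classes <- character()
  step_len <- min(width, height) / 18
  margin <- spec$cell
  # start points are stratified over the whole domain — street networks span
  # a municipality, leaving no bare corners — then the walks drift uphill so
  # attractive areas end up with the densest network
  n_roads <- length(params$road_classes) * params$roads_per_class
  n_blocks <- ceiling(sqrt(n_roads))
  blocks <- sample(rep_len(seq_len(n_blocks^2), n_roads))
  road_i <- 0L
  for (cl in params$road_classes) {
    for (j in seq_len(params$roads_per_class)) {
      road_i <- road_i + 1L
      bi <- blocks[road_i] - 1L
      bx <- bi %% n_blocks; by <- bi %/% n_blocks
      pos <- c(xmin + (bx + stats::runif(1)) * width / n_blocks,
               ymax - (by + stats::runif(1)) * height / n_blocks)
      theta <- stats::runif(1, 0, 2 * pi)
      dir <- c(cos(theta), sin(theta))
      verts <- matrix(pos, 1L, 2L)
      for (v in seq_len(11L)) {
        g <- grad_at(grad, spec, pos)
        gn <- sqrt(sum(g^2))
        if (gn > 0) g <- g / gn
        dir <- dir + 0.5 * g + 0.6 * stats::rnorm(2L)
        dir <- dir / sqrt(sum(dir^2))
        pos <- pos + step_len * dir
        pos[1L] <- min(max(pos[1L], xmin + margin), xmin + width - margin)
        pos[2L] <- min(max(pos[2L], ymax - height + margin), ymax - margin)
        verts <- rbind(verts, pos)
      }
      lines[[length(lines) + 1L]] <- unname(verts)
      classes <- c(classes, cl)
    }
  }
  roads <- road_network(lines, classes, spec$crs)

  ## 3. construction road density (equal class weights) and true density
  per_class <- lapply(params$road_classes, function(cl)
    line_kde(roads, cl, params$kde_bandwidth, spec))
  names(per_class) <- params$road_classes
  eq_w <- stats::setNames(rep(1 / length(per_class), length(per_class)),
                          names(per_class))
  rnd <- composite_rnd(per_class, eq_w)
  dens <- params$a_true * rnd$values^params$b_true + params$density_floor
  true_density <- grid_from_spec(spec, dens)

  ## 4. census zones: jittered rectangular partition on cell edges
  set.seed(sub_seed(params$seed, 3L))
  nr_rows <- max(1L, round(sqrt(params$n_zones * spec$nrow / spec$ncol)))
  nr_rows <- min(nr_rows, params$n_zones)
  per_row <- rep(params$n_zones %/% nr_rows, nr_rows)
  extra <- params$n_zones %% nr_rows
  if (extra > 0) per_row[seq_len(extra)] <- per_row[seq_len(extra)] + 1L
  row_sizes <- partition_sizes(spec$nrow, nr_rows)
  row_breaks <- c(0L, cumsum(row_sizes))
  ids <- character(); polys <- list()
  for (ri in seq_len(nr_rows)) {
    col_sizes <- partition_sizes(spec$ncol, per_row[ri])
    col_breaks <- c(0L, cumsum(col_sizes))
    y_top <- ymax - row_breaks[ri] * spec$cell
    y_bot <- ymax - row_breaks[ri + 1L] * spec$cell
    for (ci in seq_len(per_row[ri])) {
      x_l <- xmin + col_breaks[ci] * spec$cell
      x_r <- xmin + col_breaks[ci + 1L] * spec$cell
      ids <- c(ids, sprintf("z%03d", length(ids) + 1L))
      polys[[length(polys) + 1L]] <-
        list(rbind(c(x_l, y_bot), c(x_r, y_bot), c(x_r, y_top),
                   c(x_l, y_top), c(x_l, y_bot)))
    }
  }
  zones0 <- zone_set(ids, polys, crs = spec$crs)
  assign <- zone_assignment(zones0, spec)
  integral <- zonal_sum(true_density, zones0, assignment = assign) *
    cell_area_km2(spec)
  zones <- zone_set(ids, polys, population = round(integral), crs = spec$crs)

  ## 5. nighttime lights: DN such that radiance tracks the *visible* part of
  ##    density — a saturating response (light missed over the densest fabric:
  ##    underground activity, crowded low-light quarters) — plus Gaussian
  ##    blooming and multiplicative noise
  set.seed(sub_seed(params$seed, 4L))
  visible <- if (is.finite(params$ntl_saturation))
    dens * params$ntl_saturation / (dens + params$ntl_saturation) else dens
  dn_true <- visible^(2 / 3)       # inverse of L = 1e-10 * DN^(3/2), L ~ visible
  dn_blur <- gaussian_blur(dn_true, params$ntl_blur_sigma / spec$cell)
  if (params$ntl_field_sd > 0) {
    # district-scale emissivity bias: a smooth lognormal field emulating how
    # lighting per inhabitant varies with land use, building stock and
    # underground activity from one quarter to the next
    field <- gaussian_blur(matrix(stats::rnorm(length(dn_blur)),
                                  nrow(dn_blur)),
                           params$ntl_field_scale / spec$cell)
    field <- field / stats::sd(field)
    dn_blur <- dn_blur * exp(params$ntl_field_sd * field -
                               params$ntl_field_sd^2 / 2)
  }
  if (params$noise_sd > 0) {
    noise <- exp(params$noise_sd * matrix(stats::rnorm(length(dn_blur)),
                                          nrow(dn_blur)) -
                   params$noise_sd^2 / 2)
    dn_blur <- dn_blur * noise
  }
  ntl_dn <- grid_from_spec(spec, pmax(dn_blur, 0))

  ## 6. vegetation stack: greenness decays with density, modulated by a
  ##    smooth land-use field (parks inside the dense fabric, bare ground in
  ##    sparse areas), with a seasonal cycle on top
  set.seed(sub_seed(params$seed, 5L))
  green <- 0.85 * exp(-dens / 8000)
  if (params$evi_field_sd > 0) {
    vfield <- gaussian_blur(matrix(stats::rnorm(length(green)), nrow(green)),
                            params$ntl_field_scale / spec$cell)
    vfield <- vfield / stats::sd(vfield)
    green <- pmin(green * exp(params$evi_field_sd * vfield -
                                params$evi_field_sd^2 / 2), 0.9)
  }
  base <- 0.05 + green
  evi_stack <- lapply(seq_len(params$n_evi), function(t) {
    season <- 0.55 + 0.40 * cos(2 * pi * (t - 14) / params$n_evi)
    jitter <- 0.02 * matrix(stats::rnorm(length(base)), nrow(base))
    grid_from_spec(spec, pmin(pmax(base * season + jitter, -0.2), 1))
  })

  structure(list(true_density = true_density, ntl_dn = ntl_dn,
                 evi_stack = evi_stack, roads = roads, zones = zones,
                 rnd_construction = rnd, params = params),
            class = "synthetic_scene")
}

# central-difference gradient of a cell-centre field, per metre
attract_gradient <- function(a, spec) {
  nr <- nrow(a); nc <- ncol(a)
  gx <- (a[, c(2:nc, nc)] - a[, c(1L, 1:(nc - 1L))]) / (2 * spec$cell)
  gy <- (a[c(1L, 1:(nr - 1L)), ] - a[c(2:nr, nr), ]) / (2 * spec$cell)
  list(gx = gx, gy = gy)
}

grad_at <- function(grad, spec, pos) {
  c <- min(max(1L, as.integer(round((pos[1L] - spec$x0) / spec$cell + 0.5))),
           ncol(grad$gx))
  r <- min(max(1L, as.integer(round((spec$y0 - pos[2L]) / spec$cell + 0.5))),
           nrow(grad$gx))
  c(grad$gx[r, c], grad$gy[r, c])
}

#' @export
print.synthetic_scene <- function(x, ...) {
  sp <- x$params$grid
  cat(sprintf("<synthetic_scene> %d x %d cells @ %g m, seed %d\n",
              sp$nrow, sp$ncol, sp$cell, x$params$seed))
  cat(sprintf("  population %s in %d zones; %.1f km of roads\n",
              format(sum(x$zones$population), big.mark = ","),
              n_zones(x$zones), network_length(x$roads) / 1000))
  invisible(x)
}

#' Write a synthetic scene to pipeline input files
#'
#' Materialises the scene as the exact file set the pipeline consumes:
#' `ntl_dn.asc`, `evi_01.asc ... evi_NN.asc`, `roads.geojson`,
#' `zones.geojson`, `census.csv`, plus `true_density.asc` (the truth layer,
#' not a pipeline input).
#'
#' @param scene a [synthetic_scene][generate_scene].
#' @param directory output directory (created if missing).
#' @return Named list of paths: `ntl`, `evi` (vector), `roads`, `zones`,
#'   `census`, `true_density`.
#' @export
scene_to_files <- function(scene, directory) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  if (file.access(directory, 2L) != 0L)
    stop("directory not writable: ", directory, call. = FALSE)
  p <- function(f) file.path(directory, f)
  write_grid_asc(scene$ntl_dn, p("ntl_dn.asc"))
  evi_paths <- vapply(seq_along(scene$evi_stack), function(i) {
    fp <- p(sprintf("evi_%02d.asc", i))
    write_grid_asc(scene$evi_stack[[i]], fp)
    fp
  }, character(1))
  write_roads_geojson(scene$roads, p("roads.geojson"))
  write_zones_geojson(scene$zones, p("zones.geojson"),
                      census_csv = p("census.csv"))
  write_grid_asc(scene$true_density, p("true_density.asc"))
  list(ntl = p("ntl_dn.asc"), evi = evi_paths, roads = p("roads.geojson"),
       zones = p("zones.geojson"), census = p("census.csv"),
       true_density = p("true_density.asc"))
}
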