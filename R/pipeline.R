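#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent named list), checks it
#' against the pipeline schema and fills defaults: 100 m analysis grid taken
#' from the NTL raster, radiance exponent 3/2, 3000 m bandwidth, regression
#' disaggregation. All schema violations are reported together; required
#' fields are never silently defaulted.
#'
#' @param config path to a YAML file, or a named list.
#' @return Object of class `pipeline_config` (validated list). The source
#'   path (when read from file) is kept in attribute `"path"`.
#' @export
validate_config <- function(config) {
  path <- NULL
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("no such config file: ", config,
                                   call. = FALSE)
    path <- config
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML file or a list",
                             call. = FALSE)
  errs <- character()
  need <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  def <- function(x, d) if (is.null(x)) d else x

  inp <- config$inputs
  need(is.list(inp), "inputs: required block with ntl, evi, roads, zones")
  if (is.list(inp)) {
    for (f in c("ntl", "roads", "zones"))
      need(is.character(inp[[f]]) && length(inp[[f]]) == 1L,
           sprintf("inputs.%s: required single path", f))
    need(is.character(unlist(inp$evi)) && length(unlist(inp$evi)) >= 1L,
         "inputs.evi: required list of raster paths")
    inp$evi <- as.character(unlist(inp$evi))
  }

  out <- list(
    inputs = inp,
    radiance_exponent = def(config$radiance_exponent, 1.5),
    radiance_scale = def(config$radiance_scale, 1e-10),
    evi_clamp = def(config$evi_clamp, TRUE),
    hsi_eps = def(config$hsi_eps, 1e-9),
    bandwidth = def(config$bandwidth, 3000),
    bandwidths = def(config$bandwidths, 3000),
    bandwidth_choose = def(config$bandwidth_choose, "default"),
    kde_spacing_factor = def(config$kde_spacing_factor, 0.25),
    rnd_exponent = config$rnd_exponent,  # NULL = fit from census
    power_fit_nonlinear = def(config$power_fit_nonlinear, FALSE),
    disaggregation_mode = def(config$disaggregation_mode, "regression"),
    output_dir = config$output_dir,
    seed = def(config$seed, 1L))

  need(is.numeric(out$radiance_exponent) && out$radiance_exponent > 0,
       "radiance_exponent: must be a positive number")
  need(is.numeric(out$bandwidth) && length(out$bandwidth) == 1L &&
         out$bandwidth > 0,
       "bandwidth: must be a single positive number of metres")
  out$bandwidths <- as.numeric(unlist(out$bandwidths))
  need(length(out$bandwidths) >= 1L && all(out$bandwidths > 0) &&
         !is.unsorted(out$bandwidths, strictly = TRUE),
       "bandwidths: must be strictly increasing positive metres")
  need(out$bandwidth_choose %in% c("default", "max_mean_r"),
       "bandwidth_choose: must be 'default' or 'max_mean_r'")
  need(is.numeric(out$kde_spacing_factor) && out$kde_spacing_factor > 0,
       "kde_spacing_factor: must be positive")
  need(is.null(out$rnd_exponent) ||
         (is.numeric(out$rnd_exponent) && out$rnd_exponent >= 0),
       "rnd_exponent: must be omitted (fit from census), 0 (HSI-only) or > 0")
  modes <- c("regression", "proportional", "proportional_by_zone")
  need(out$disaggregation_mode %in% modes,
       sprintf("disaggregation_mode: '%s' is not one of %s",
               out$disaggregation_mode, paste(modes, collapse = ", ")))
  need(is.logical(out$evi_clamp), "evi_clamp: must be true/false")

  if (length(errs))
    stop("invalid pipeline config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  structure(out, class = "pipeline_config", path = path)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  cfg <- unclass(config)
  attr(cfg, "path") <- NULL
  yaml::write_yaml(cfg, tf)
  unname(tools::md5sum(tf))
}

#' Run the full population-mapping pipeline
#'
#' Sequences the whole workflow on the configured inputs: align layers onto
#' the analysis grid, DN-to-radiance conversion, study-area min-max
#' normalisation, vegetation maximum compositing, HSI, per-class road kernel
#' densities, (optional) bandwidth sweep, PCA class weights, composite road
#' density, power-law calibration of the exponent, RNAHSI, linear zonal
#' calibration, correction factor, disaggregation, density conversion and
#' the accuracy report. With `rnd_exponent = 0` the road-density adjustment
#' is switched off and the HSI itself is calibrated and disaggregated (the
#' baseline the adjusted index is compared against).
#'
#' When `config$output_dir` is set, writes `hsi.asc`, `rnd.asc`,
#' `rnahsi.asc`, `population.asc`, `density.asc`, `sweep.csv`,
#' `weights.json`, `powerfit.json`, `accuracy.json`, `accuracy_zones.csv`
#' and `run_log.txt` (per-stage timings, input hashes, dropped-zone counts,
#' config hash and package version). `accuracy.json` holds metrics only, so
#' identical configs and inputs produce byte-identical reports.
#'
#' @param config a [pipeline_config][validate_config], or a path/list
#'   accepted by it.
#' @param scene optional [synthetic_scene][generate_scene] supplying the
#'   inputs in memory (the `inputs` block is then ignored).
#' @return Invisibly, a list with the intermediate grids (`hsi`, `rnd`,
#'   `rnahsi`, `population`, `density`), `weights`, `power_fit`,
#'   `linear_fit`, `correction_factor`, `sweep` (or `NULL`), `report`
#'   (an `accuracy_report`) and `log` (character).
#' @export
run_pipeline <- function(config, scene = NULL) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  log <- character()
  t_all <- proc.time()[[3L]]
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[[3L]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    say("stage %-18s %6.2f s", name, proc.time()[[3L]] - t0)
    res
  }
  say("pipeline config hash %s, rnahsi version %s",
      config_hash(config), as.character(utils::packageVersion("rnahsi")))

  ## -- load inputs ---------------------------------------------------------
  if (is.null(scene)) {
    ntl <- stage("read_ntl", read_grid_asc(config$inputs$ntl))
    evi_list <- stage("read_evi",
                      lapply(config$inputs$evi, read_grid_asc))
    roads <- stage("read_roads",
                   read_roads_geojson(config$inputs$roads, crs = ntl$crs))
    zones <- stage("read_zones",
                   read_zones_geojson(config$inputs$zones,
                                      census_csv = config$inputs$census,
                                      crs = ntl$crs))
    for (f in c("ntl", "roads", "zones"))
      say("input %s md5 %s", f, unname(tools::md5sum(config$inputs[[f]])))
  } else {
    stopifnot(inherits(scene, "synthetic_scene"))
    ntl <- scene$ntl_dn; evi_list <- scene$evi_stack
    roads <- scene$roads; zones <- scene$zones
    say("inputs taken from in-memory synthetic scene (seed %d)",
        scene$params$seed)
  }
  target <- grid_spec_of(ntl)

  ## -- preprocessing -------------------------------------------------------
  evi_list <- stage("align", align_stack(evi_list, target))
  radiance <- stage("radiance",
                    dn_to_radiance(ntl, exponent = config$radiance_exponent,
                                   scale = config$radiance_scale))
  assign <- stage("zone_assignment", zone_assignment(zones, target))
  mask <- assign > 0L
  lj_nor <- stage("normalize",
                  minmax_normalize(radiance, mask = mask,
                                   clip_to_mask = TRUE))
  evi_max <- stage("evi_composite", max_composite(evi_list))
  if (config$evi_clamp) evi_max$values <- pmax(evi_max$values, 0)
  evi_max$values[!mask] <- NA_real_
  hsi <- stage("hsi", compute_hsi(evi_max, lj_nor, eps = config$hsi_eps,
                                  clamp_evi = config$evi_clamp))

  ## -- road network density ------------------------------------------------
  sweep <- NULL
  if (length(config$bandwidths) >= 2L)
    sweep <- stage("bandwidth_sweep",
                   bandwidth_sweep(roads, zones, config$bandwidths, target,
                                   choose = config$bandwidth_choose,
                                   default_bandwidth = config$bandwidth,
                                   spacing_factor = config$kde_spacing_factor))
  bw <- if (!is.null(sweep)) sweep$chosen else config$bandwidth
  say("bandwidth %g m", bw)
  classes <- sort(unique(roads$classes))
  per_class <- stage("line_kde", {
    g <- lapply(classes, function(cl)
      line_kde(roads, cl, bw, target,
               spacing_factor = config$kde_spacing_factor))
    names(g) <- classes
    g
  })
  zsums <- vapply(per_class, zonal_sum, numeric(n_zones(zones)),
                  zones = zones, assignment = assign)
  weights <- stage("pca_weights", pca_class_weights(zsums))
  rnd <- stage("composite_rnd", composite_rnd(per_class, weights))

  ## -- index calibration ---------------------------------------------------
  hsi_only <- !is.null(config$rnd_exponent) && config$rnd_exponent == 0
  mean_rnd <- zonal_sum(rnd, zones, assignment = assign) / zones$area_km2
  mean_density <- zones$population / zones$area_km2
  power_fit <- stage("power_fit",
                     fit_power_law(mean_rnd, mean_density,
                                   nonlinear = config$power_fit_nonlinear))
  say("power fit: a = %.6g, b = %.4f, R^2 = %.3f (%d zones, %d dropped)",
      power_fit$a, power_fit$b, power_fit$r_squared, power_fit$n_zones,
      power_fit$n_dropped)
  index <- if (hsi_only) {
    say("rnd_exponent = 0: HSI-only mode, road adjustment disabled")
    hsi
  } else {
    b <- if (is.null(config$rnd_exponent)) power_fit$b else config$rnd_exponent
    stage("rnahsi", compute_rnahsi(hsi, rnd, b))
  }

  ## -- population mapping --------------------------------------------------
  zsum_index <- zonal_sum(index, zones, assignment = assign)
  lin_fit <- stage("linear_calibration",
                   fit_linear_calibration(zsum_index, zones$population))
  population <- stage("disaggregate",
                      disaggregate(index, zones, fit = lin_fit,
                                   mode = config$disaggregation_mode,
                                   assignment = assign))
  cf <- attr(population, "correction_factor")
  if (!is.na(cf)) say("correction factor %.4f", cf)
  density <- stage("to_density", to_density(population))
  report <- stage("assessment",
                  residual_report(population, zones, assignment = assign))
  say("accuracy: MRE %.2f%%, %%RMSE %.2f%%, R^2 %.3f",
      report$mre, report$pct_rmse, report$r_squared)

  ## -- outputs -------------------------------------------------------------
  if (!is.null(config$output_dir)) {
    od <- config$output_dir
    if (!dir.exists(od)) dir.create(od, recursive = TRUE)
    p <- function(f) file.path(od, f)
    write_grid_asc(hsi, p("hsi.asc"))
    write_grid_asc(rnd, p("rnd.asc"))
    write_grid_asc(index, p("rnahsi.asc"))
    write_grid_asc(population, p("population.asc"))
    write_grid_asc(density, p("density.asc"))
    sweep_df <- if (!is.null(sweep)) sweep_table(sweep) else
      data.frame(bandwidth = bw, road_class = classes,
                 r = vapply(classes, function(cl)
                   suppressWarnings(stats::cor(zsums[, cl],
                                               zones$population)),
                   numeric(1)))
    utils::write.csv(sweep_df, p("sweep.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(weights = as.list(weights$weights),
           variance_explained = weights$variance_explained,
           eigenvalues = weights$eigenvalues),
      p("weights.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(a = power_fit$a, b = power_fit$b,
           r_squared = power_fit$r_squared, n_zones = power_fit$n_zones,
           n_dropped = power_fit$n_dropped,
           linear_slope = lin_fit$slope, linear_intercept = lin_fit$intercept,
           linear_r_squared = lin_fit$r_squared,
           correction_factor = cf),
      p("powerfit.json"), auto_unbox = TRUE, digits = NA)
    write_accuracy_report(report, p("accuracy_zones.csv"),
                          p("accuracy.json"))
    say("11 outputs written to %s", od)
    writeLines(log, p("run_log.txt"))
  }
  say("pipeline done in %.1f s", proc.time()[[3L]] - t_all)
  invisible(list(hsi = hsi, rnd = rnd, rnahsi = index,
                 population = population, density = density,
                 weights = weights, power_fit = power_fit,
                 linear_fit = lin_fit, correction_factor = cf,
                 sweep = sweep, report = report, log = log))
}
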