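#' Linear calibration of zonal index sums against census counts
#'
#' Ordinary least squares of zone population on the zonal sum of an index
#' surface — the regression whose fit quality (R^2) is the headline
#' comparison between candidate indices.
#'
#' @param zonal_index_sums per-zone sums of the index raster (not all equal).
#' @param populations per-zone census counts (same length, >= 3 zones).
#' @return Object of class `linear_fit`: list with `slope`, `intercept`,
#'   `r_squared`. A constant response fits exactly (slope 0) and reports
#'   `r_squared = 1` (zero residuals).
#' @export
fit_linear_calibration <- function(zonal_index_sums, populations) {
  x <- as.numeric(zonal_index_sums); y <- as.numeric(populations)
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 zones", call. = FALSE)
  if (stats::var(x) == 0)
    stop("degenerate predictor: all zonal index sums are equal", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::resid(fit)^2) / sst
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> population = %.6g * sum + %.6g (R^2 = %.3f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Total-population correction factor
#'
#' Ratio of the actual (census) total to the estimated total, applied to the
#' estimated raster to remove overall bias.
#'
#' @param estimated_total estimated study-area total, > 0.
#' @param actual_total census total.
#' @return The ratio `actual_total / estimated_total`.
#' @export
correction_factor <- function(estimated_total, actual_total) {
  if (!is.numeric(estimated_total) || estimated_total <= 0)
    stop("estimated total must be positive", call. = FALSE)
  actual_total / estimated_total
}

#' Disaggregate census counts onto the grid
#'
#' Turns an index surface into a persons-per-cell raster, conserving the
#' census total exactly. Modes:
#' \describe{
#'   \item{`regression`}{pixel value = `slope * index + intercept / n_cells`
#'     (the intercept spread uniformly over the in-area cells), negatives
#'     clipped to 0, then the whole surface rescaled by the correction factor
#'     so the study-area total equals the census total.}
#'   \item{`proportional`}{`total_census * index / sum(index)` — exact
#'     study-area conservation by construction.}
#'   \item{`proportional_by_zone`}{the same within each zone with that zone's
#'     census count — exact per-zone conservation. A zone whose index is all
#'     zero but whose census is positive is spread uniformly (with a
#'     warning).}
#' }
#' Cells outside every zone become `NA`.
#'
#' @param rnahsi index [rn_grid] (RNAHSI, or HSI for the unadjusted map).
#' @param zones a [zone_set] with complete census counts.
#' @param fit a `linear_fit` (required for `regression` mode).
#' @param mode one of `"regression"`, `"proportional"`,
#'   `"proportional_by_zone"`.
#' @param assignment optional precomputed [zone_assignment].
#' @return [rn_grid] of persons per cell, with attribute
#'   `"correction_factor"` in regression mode.
#' @export
disaggregate <- function(rnahsi, zones, fit = NULL,
                         mode = c("regression", "proportional",
                                  "proportional_by_zone"),
                         assignment = NULL) {
  mode <- match.arg(mode)
  stopifnot(is_rn_grid(rnahsi), inherits(zones, "zone_set"))
  if (anyNA(zones$population))
    stop("zones have missing census counts; join the census first",
         call. = FALSE)
  if (is.null(assignment))
    assignment <- zone_assignment(zones, grid_spec_of(rnahsi))
  v <- rnahsi$values
  in_area <- assignment > 0L & !is.na(v)
  n_area <- sum(in_area)
  if (n_area == 0L) stop("no usable cells inside the zones", call. = FALSE)
  census_total <- sum(zones$population)
  out <- matrix(NA_real_, nrow(v), ncol(v))
  if (mode == "regression") {
    if (!inherits(fit, "linear_fit"))
      stop("regression mode needs a `linear_fit`", call. = FALSE)
    raw <- fit$slope * v[in_area] + fit$intercept / n_area
    raw[raw < 0] <- 0
    est_total <- sum(raw)
    if (est_total <= 0)
      stop("regression predicts a non-positive total; cannot rescale",
           call. = FALSE)
    cf <- correction_factor(est_total, census_total)
    out[in_area] <- raw * cf
  } else if (mode == "proportional") {
    w <- pmax(v[in_area], 0)
    tot <- sum(w)
    if (tot == 0) {
      warning("index is zero everywhere in the study area; spreading the ",
              "census uniformly", call. = FALSE)
      out[in_area] <- census_total / n_area
    } else out[in_area] <- census_total * w / tot
    cf <- NA_real_
  } else {
    for (zi in seq_len(n_zones(zones))) {
      sel <- assignment == zi & !is.na(v)
      nz_cells <- sum(sel)
      if (nz_cells == 0L) next
      w <- pmax(v[sel], 0)
      tot <- sum(w)
      pz <- zones$population[zi]
      if (tot == 0) {
        if (pz > 0)
          warning("zone ", zones$zone_id[zi], " has zero index but census ",
                  pz, "; spreading uniformly", call. = FALSE)
        out[sel] <- pz / nz_cells
      } else out[sel] <- pz * w / tot
    }
    cf <- NA_real_
  }
  g <- rnahsi
  g$values <- out
  attr(g, "correction_factor") <- cf
  g
}

#' Persons-per-cell to density per 0.01 km^2
#'
#' Converts a population raster to the density unit of the final map,
#' individuals per 0.01 km^2 (one hectare) — the identity for a 100 m grid,
#' where each cell covers exactly 0.01 km^2.
#'
#' @param pop [rn_grid] of persons per cell.
#' @return [rn_grid] of persons per 0.01 km^2.
#' @export
to_density <- function(pop) {
  stopifnot(is_rn_grid(pop))
  out <- pop
  out$values <- pop$values / (cell_area_km2(pop) / 0.01)
  out
}
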