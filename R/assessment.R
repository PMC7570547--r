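#' Mean relative error (percent)
#'
#' `MRE = 100 * (1/n) * sum |PE_i - P_i| / P_i` over zones — the mean
#' oscillation amplitude of the deviation between estimated and actual
#' counts.
#'
#' @param estimates estimated zone populations `PE_i`.
#' @param actuals actual zone populations `P_i`, all > 0.
#' @param zone_id optional ids for error messages.
#' @return MRE in percent.
#' @export
mre <- function(estimates, actuals, zone_id = NULL) {
  check_zonal_pair(estimates, actuals)
  zero <- actuals <= 0
  if (any(zero)) {
    who <- if (is.null(zone_id)) which(zero)[1L] else zone_id[zero][1L]
    stop("zone ", who, " has non-positive census population; MRE undefined",
         call. = FALSE)
  }
  100 * mean(abs(estimates - actuals) / actuals)
}

#' Percent root-mean-square error
#'
#' `%RMSE = 100 * sqrt(sum (PE_i - P_i)^2 / n) / M_pop`, the RMSE of the
#' zonal estimates divided by the mean zone population `M_pop`.
#'
#' @inheritParams mre
#' @return %RMSE in percent.
#' @export
pct_rmse <- function(estimates, actuals, zone_id = NULL) {
  check_zonal_pair(estimates, actuals)
  m_pop <- mean(actuals)
  if (m_pop <= 0) stop("mean census population must be positive", call. = FALSE)
  100 * sqrt(mean((estimates - actuals)^2)) / m_pop
}

check_zonal_pair <- function(estimates, actuals) {
  if (length(estimates) != length(actuals) || length(actuals) < 1L)
    stop("estimates and actuals must be equal-length, non-empty vectors",
         call. = FALSE)
  if (anyNA(estimates) || anyNA(actuals))
    stop("missing values in estimates/actuals", call. = FALSE)
  invisible(TRUE)
}

#' Coefficient of determination between zonal estimates and census
#'
#' Primary definition: squared Pearson correlation between `PE` and `P` (the
#' scatter-fit reading of a calibration plot). `method = "identity"` instead
#' gives `1 - SSE/SST` of the residuals about the identity line `PE = P`,
#' which penalises bias as well as scatter. Zero variance in either variable
#' makes the Pearson version undefined: `NA` is returned with a warning.
#'
#' @inheritParams mre
#' @param method `"pearson"` (default) or `"identity"`.
#' @return R^2, or `NA` when undefined.
#' @export
r_squared <- function(estimates, actuals, method = c("pearson", "identity")) {
  method <- match.arg(method)
  check_zonal_pair(estimates, actuals)
  if (method == "identity") {
    sst <- sum((actuals - mean(actuals))^2)
    if (sst == 0) {
      warning("zero variance in census counts; R^2 undefined", call. = FALSE)
      return(NA_real_)
    }
    return(1 - sum((estimates - actuals)^2) / sst)
  }
  if (length(actuals) < 3L)
    stop("need at least 3 zones for R^2", call. = FALSE)
  if (stats::sd(estimates) == 0 || stats::sd(actuals) == 0) {
    warning("zero variance; R^2 undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(estimates, actuals)^2
}

#' Per-zone residuals and accuracy summary for a population raster
#'
#' Sums the estimated population raster over the census zones and reports
#' per-zone residuals `PE_i - P_i` together with the three summary metrics
#' (MRE, %RMSE, R^2) — the table behind zone-level residual maps and the
#' three-way comparison of candidate population products.
#'
#' @param pop_grid [rn_grid] of estimated persons per cell (any product:
#'   the road-adjusted map, the unadjusted map, or an external raster
#'   aligned to the grid).
#' @param zones a [zone_set] with census counts > 0.
#' @param assignment optional precomputed [zone_assignment].
#' @return Object of class `accuracy_report`: list with `residuals`
#'   (data.frame: zone_id, estimated, census, residual), `mre`, `pct_rmse`,
#'   `r_squared` (Pearson^2), `r_squared_identity`.
#' @export
residual_report <- function(pop_grid, zones, assignment = NULL) {
  stopifnot(is_rn_grid(pop_grid), inherits(zones, "zone_set"))
  pe <- zonal_sum(pop_grid, zones, assignment = assignment)
  p <- zones$population
  res <- data.frame(zone_id = zones$zone_id,
                    estimated = unname(pe),
                    census = p,
                    residual = unname(pe) - p,
                    stringsAsFactors = FALSE)
  structure(list(residuals = res,
                 mre = mre(pe, p, zone_id = zones$zone_id),
                 pct_rmse = pct_rmse(pe, p),
                 r_squared = r_squared(pe, p, method = "pearson"),
                 r_squared_identity = r_squared(pe, p, method = "identity")),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report>\n")
  cat(sprintf("  MRE    %.2f%%\n", x$mre))
  cat(sprintf("  %%RMSE  %.2f%%\n", x$pct_rmse))
  cat(sprintf("  R^2    %.3f (Pearson^2; identity-line %.3f)\n",
              x$r_squared, x$r_squared_identity))
  cat(sprintf("  zones  %d\n", nrow(x$residuals)))
  invisible(x)
}

#' Write an accuracy report to CSV + JSON
#' @param report an `accuracy_report`.
#' @param csv_path per-zone residual table destination.
#' @param json_path summary metrics destination.
#' @return `invisible(report)`.
#' @export
write_accuracy_report <- function(report, csv_path, json_path) {
  stopifnot(inherits(report, "accuracy_report"))
  utils::write.csv(report$residuals, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(mre_pct = report$mre, pct_rmse = report$pct_rmse,
         r_squared = report$r_squared,
         r_squared_identity = report$r_squared_identity,
         n_zones = nrow(report$residuals)),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
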