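#' Human settlement index (HSI)
#'
#' Combines the annual-maximum vegetation index and the normalised
#' nighttime-light layer into
#' `HSI = (1 - EVI_max + LJ_nor) / ((1 - LJ_nor) + EVI_max + LJ_nor * EVI_max)`,
#' which is high where light is strong and vegetation sparse (built-up /
#' impervious settlement) and low where vegetation dominates. The denominator
#' vanishes at `(LJ_nor, EVI_max) = (1, 0)`; it is floored at `eps` so the
#' index stays finite (value `2/eps` at the degenerate corner) while regular
#' cells are computed exactly.
#'
#' @param evi_max [rn_grid], annual maximum vegetation index. Values below 0
#'   are clamped to 0 when `clamp_evi` (water/bare surfaces); after clamping
#'   all values must lie in \[0, 1\].
#' @param lj_nor [rn_grid], min-max normalised radiance in \[0, 1\], aligned
#'   with `evi_max`.
#' @param eps denominator floor (default 1e-9).
#' @param clamp_evi clamp negative EVI to 0 (default `TRUE`).
#' @return [rn_grid] of HSI; `NA` propagated.
#' @export
compute_hsi <- function(evi_max, lj_nor, eps = 1e-9, clamp_evi = TRUE) {
  stopifnot(is_rn_grid(evi_max), is_rn_grid(lj_nor))
  mm <- alignment_mismatch(evi_max, lj_nor)
  if (nzchar(mm)) stop("EVI and NTL grids misaligned: ", mm, " differs",
                       call. = FALSE)
  e <- evi_max$values
  if (clamp_evi) e <- pmax(e, 0)
  l <- lj_nor$values
  tol <- 1e-12
  if (any(e < -tol | e > 1 + tol, na.rm = TRUE))
    stop("EVI_max out of [0, 1] after clamping", call. = FALSE)
  if (any(l < -tol | l > 1 + tol, na.rm = TRUE))
    stop("LJ_nor out of [0, 1]; normalise (and clip to the study area) first",
         call. = FALSE)
  num <- 1 - e + l
  den <- pmax((1 - l) + e + l * e, eps)
  out <- evi_max
  out$values <- num / den
  out
}

#' Power-law fit of census density on road-network density
#'
#' Fits `density = a * RND^b` by ordinary least squares of `log(density)` on
#' `log(RND)` — the straight-line-on-log-axes reading of the zone-level
#' scatter. Zones with non-positive mean RND or density are dropped (log
#' undefined) with a message. The exponent `b` is unit-invariant; the
#' coefficient `a` is in density units per RND^b and must be refitted if the
#' RND units change.
#'
#' @param mean_rnd per-zone mean road-network density (> 0 to be used).
#' @param mean_density per-zone census density, persons/km^2 (> 0 to be
#'   used).
#' @param nonlinear refine by nonlinear least squares on the original scale
#'   after the log-log fit (default `FALSE`).
#' @return Object of class `power_law_fit`: list with `a`, `b`, `r_squared`,
#'   `n_zones` (used), `n_dropped`.
#' @export
fit_power_law <- function(mean_rnd, mean_density, nonlinear = FALSE) {
  if (length(mean_rnd) != length(mean_density))
    stop("mean_rnd and mean_density must have equal length", call. = FALSE)
  ok <- is.finite(mean_rnd) & is.finite(mean_density) &
    mean_rnd > 0 & mean_density > 0
  n_drop <- sum(!ok)
  if (n_drop > 0)
    message(n_drop, " zone(s) dropped from the power fit (non-positive ",
            "RND or density)")
  if (sum(ok) < 3L)
    stop("fewer than 3 usable zones for the power-law fit", call. = FALSE)
  lx <- log(mean_rnd[ok]); ly <- log(mean_density[ok])
  fit <- stats::lm(ly ~ lx)
  b <- unname(stats::coef(fit)[2L])
  a <- exp(unname(stats::coef(fit)[1L]))
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::resid(fit)^2) / sst
  if (nonlinear) {
    nls_fit <- try(stats::nls(y ~ a * x^b,
                              data = data.frame(x = mean_rnd[ok],
                                                y = mean_density[ok]),
                              start = list(a = a, b = b)), silent = TRUE)
    if (!inherits(nls_fit, "try-error")) {
      cf <- stats::coef(nls_fit)
      a <- unname(cf[["a"]]); b <- unname(cf[["b"]])
    }
  }
  structure(list(a = a, b = b, r_squared = r2,
                 n_zones = sum(ok), n_dropped = n_drop),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> density = %.4g * RND^%.4f (R^2 = %.3f, n = %d",
              x$a, x$b, x$r_squared, x$n_zones))
  if (x$n_dropped > 0) cat(sprintf(", %d dropped", x$n_dropped))
  cat(")\n")
  invisible(x)
}

#' Road network adjusted HSI (RNAHSI)
#'
#' Adjusts the settlement index by the road-network density raised to the
#' census-calibrated exponent: `RNAHSI = HSI * RND^b` per cell. With `b > 0`,
#' zero road density forces the index to zero, concentrating the settlement
#' signal on the road-served fabric of the city.
#'
#' @param hsi [rn_grid] from [compute_hsi].
#' @param rnd aligned non-negative [rn_grid] from [composite_rnd], in the
#'   same units used when fitting the exponent.
#' @param exponent the fitted power-law exponent `b` (> 0).
#' @return [rn_grid] of RNAHSI; `NA` propagated.
#' @export
compute_rnahsi <- function(hsi, rnd, exponent) {
  stopifnot(is_rn_grid(hsi), is_rn_grid(rnd))
  mm <- alignment_mismatch(hsi, rnd)
  if (nzchar(mm)) stop("HSI and RND grids misaligned: ", mm, " differs",
                       call. = FALSE)
  if (!is.numeric(exponent) || length(exponent) != 1L || exponent <= 0)
    stop("exponent must be a single positive number (density must increase ",
         "with road density)", call. = FALSE)
  if (any(rnd$values < 0, na.rm = TRUE))
    stop("RND must be non-negative", call. = FALSE)
  out <- hsi
  out$values <- hsi$values * rnd$values^exponent
  out
}
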