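#' Convert nighttime-light digital numbers to radiance
#'
#' Applies the absolute radiometric calibration of the Luojia 1-01 sensor,
#' `L = 1e-10 * DN^(3/2)`, giving radiance in W/(m^2 sr um). The exponent is
#' exposed because calibration conventions differ between NTL products.
#'
#' @param dn_grid [rn_grid] of non-negative digital numbers.
#' @param exponent calibration exponent (default 3/2).
#' @param scale calibration scale (default 1e-10).
#' @return [rn_grid] of radiance, aligned with the input; `NA` propagated.
#' @export
dn_to_radiance <- function(dn_grid, exponent = 1.5, scale = 1e-10) {
  stopifnot(is_rn_grid(dn_grid))
  v <- dn_grid$values
  neg <- !is.na(v) & v < 0
  if (any(neg)) {
    idx <- which(neg, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative DN %g at cell (%d, %d); DN must be >= 0",
                 v[idx[1L], idx[2L]], idx[1L], idx[2L]), call. = FALSE)
  }
  out <- dn_grid
  out$values <- scale * v^exponent
  out
}

#' Min-max normalise a grid to \[0, 1\]
#'
#' Rescales `(v - v_min) / (v_max - v_min)` where the minimum and maximum are
#' taken over non-`NA` cells inside `mask` (the study area — here, the union
#' of the census zones), or over the whole grid when `mask` is `NULL`. Cells
#' outside the mask are still rescaled with the in-mask extrema (and may fall
#' outside \[0, 1\]) unless `clip_to_mask` is set, in which case they become
#' `NA` — the usual study-area clip before index computation.
#'
#' @param grid [rn_grid].
#' @param mask `NULL`, a logical matrix of the grid's shape, or a
#'   [zone_set] whose union defines the mask.
#' @param clip_to_mask set out-of-mask cells to `NA` (default `FALSE`).
#' @return [rn_grid] with in-mask values in \[0, 1\]; `NA` propagated.
#' @export
minmax_normalize <- function(grid, mask = NULL, clip_to_mask = FALSE) {
  stopifnot(is_rn_grid(grid))
  v <- grid$values
  m <- resolve_mask(mask, grid_spec_of(grid))
  sel <- if (is.null(m)) !is.na(v) else m & !is.na(v)
  if (sum(sel) < 2L)
    stop("need at least two non-nodata cells in the mask to normalise",
         call. = FALSE)
  vmin <- min(v[sel]); vmax <- max(v[sel])
  if (vmax == vmin)
    stop(sprintf(paste0("degenerate normalisation: all in-mask values equal ",
                        "%g (max = min)"), vmin), call. = FALSE)
  out <- grid
  out$values <- (v - vmin) / (vmax - vmin)
  if (clip_to_mask && !is.null(m)) out$values[!m] <- NA_real_
  out
}

# mask -> logical matrix (TRUE = in mask) or NULL
resolve_mask <- function(mask, spec) {
  if (is.null(mask)) return(NULL)
  if (is.matrix(mask) && is.logical(mask)) {
    if (!identical(dim(mask), c(spec$nrow, spec$ncol)))
      stop("logical mask shape does not match grid", call. = FALSE)
    return(mask)
  }
  if (inherits(mask, "zone_set")) return(zone_assignment(mask, spec) > 0L)
  stop("mask must be NULL, a logical matrix or a zone_set", call. = FALSE)
}

#' Per-cell maximum composite of aligned grids
#'
#' The maximum-value compositing used to build a cloud-free annual EVI layer
#' from the 16-day scenes: each output cell is the maximum over the stack,
#' ignoring `NA`; a cell is `NA` only where every input is `NA`.
#'
#' @param grids list of aligned [rn_grid] objects (length >= 1).
#' @return [rn_grid] aligned with the inputs.
#' @export
max_composite <- function(grids) {
  if (!is.list(grids) || length(grids) < 1L)
    stop("need a non-empty list of grids", call. = FALSE)
  stopifnot(all(vapply(grids, is_rn_grid, logical(1))))
  for (i in seq_along(grids)[-1L]) {
    mm <- alignment_mismatch(grids[[1L]], grids[[i]])
    if (nzchar(mm))
      stop(sprintf("grid %d is misaligned with grid 1: %s differs", i, mm),
           call. = FALSE)
  }
  out <- grids[[1L]]
  # pmax(na.rm = TRUE) is NA only where every input is NA
  out$values <- Reduce(function(a, b) pmax(a, b, na.rm = TRUE),
                       lapply(grids, function(g) g$values))
  out
}

#' Bilinear resampling onto a target grid
#'
#' Values are interpolated at the target cell centres from the four
#' surrounding source cell centres. A target cell whose (non-zero-weight)
#' 2 x 2 support contains `NA` or falls outside the source centre lattice
#' becomes `NA`. Exact for affine surfaces, hence value-preserving for the
#' identity resample.
#'
#' @param grid source [rn_grid].
#' @param target [rn_grid_spec] in the same CRS; cell size within a factor
#'   of 10 of the source.
#' @return [rn_grid] on `target`.
#' @export
resample_bilinear <- function(grid, target) {
  stopifnot(is_rn_grid(grid), inherits(target, "rn_grid_spec"))
  if (!identical(grid$crs, target$crs))
    stop(sprintf("CRS mismatch: source '%s' vs target '%s'; reproject first",
                 grid$crs, target$crs), call. = FALSE)
  ratio <- target$cell / grid$cell
  if (ratio < 0.1 || ratio > 10)
    stop("target cell size must be within [1/10, 10] of the source",
         call. = FALSE)
  if (spec_equal(grid_spec_of(grid), target))
    return(grid_from_spec(target, grid$values, grid$nodata))
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  ctr <- cell_centres(target)
  # fractional source indices: source col c has centre index c
  cf <- (ctr$x - grid$x0) / grid$cell + 0.5
  rf <- (grid$y0 - ctr$y) / grid$cell + 0.5
  eps <- 1e-9
  interp1 <- function(f, n) {
    i0 <- floor(f); t <- f - i0
    # snap to the lattice when the fractional part is numerically zero
    snap <- t < eps; t[snap] <- 0
    hi <- t > 1 - eps; i0[hi] <- i0[hi] + 1L; t[hi] <- 0
    list(i0 = as.integer(i0), t = t)
  }
  cx <- interp1(cf, nc); ry <- interp1(rf, nr)
  out <- matrix(NA_real_, target$nrow, target$ncol)
  at <- function(r, c) {
    ok <- r >= 1L & r <= nr & c >= 1L & c <= nc
    res <- rep(NA_real_, length(r))
    res[ok] <- v[cbind(r[ok], c[ok])]
    res
  }
  for (i in seq_len(target$nrow)) {
    r0 <- ry$i0[i]; u <- ry$t[i]
    c0 <- cx$i0; t <- cx$t
    w00 <- (1 - u) * (1 - t); w01 <- (1 - u) * t
    w10 <- u * (1 - t); w11 <- u * t
    v00 <- at(rep(r0, target$ncol), c0)
    v01 <- at(rep(r0, target$ncol), c0 + 1L)
    v10 <- at(rep(r0 + 1L, target$ncol), c0)
    v11 <- at(rep(r0 + 1L, target$ncol), c0 + 1L)
    term <- function(w, val) ifelse(w <= eps, 0, w * val)  # zero-weight NAs ignorable
    s <- term(w00, v00) + term(w01, v01) + term(w10, v10) + term(w11, v11)
    out[i, ] <- s
  }
  grid_from_spec(target, out, grid$nodata)
}

#' Align a stack of grids onto a common analysis grid
#'
#' Resamples every grid (bilinear) onto `target`; grids already on `target`
#' pass through unchanged. All inputs must share the target CRS.
#'
#' @param grids list of [rn_grid].
#' @param target [rn_grid_spec].
#' @return List of grids, all aligned on `target`.
#' @export
align_stack <- function(grids, target) {
  stopifnot(is.list(grids), inherits(target, "rn_grid_spec"))
  lapply(grids, resample_bilinear, target = target)
}
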