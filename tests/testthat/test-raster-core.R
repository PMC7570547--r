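test_that("radiance conversion follows the calibration power law", {
  g <- mk_grid(matrix(c(0, 1, 1e4, NA), 2, 2))
  L <- dn_to_radiance(g)
  expect_identical(L$values[1, 1], 0)
  expect_equal(L$values[2, 1], 1e-10)
  expect_equal(L$values[1, 2], 1e-4)          # (1e4)^1.5 * 1e-10
  expect_true(is.na(L$values[2, 2]))
  expect_true(grids_aligned(g, L))
})

test_that("radiance conversion rejects negative DN, naming the cell", {
  g <- mk_grid(matrix(c(3, -2, 5, 7), 2, 2))
  expect_error(dn_to_radiance(g), "\\(2, 1\\)")
})

test_that("radiance conversion is strictly increasing in DN", {
  set.seed(7)
  dn <- sort(runif(200, 0, 5000))
  out <- dn_to_radiance(mk_grid(matrix(dn, 1)))$values
  expect_true(all(diff(as.vector(out)) > 0))
})

test_that("min-max normalisation maps extremes to 0 and 1", {
  g <- mk_grid(matrix(c(0, 5, 10), 1))
  expect_equal(as.vector(minmax_normalize(g)$values), c(0, 0.5, 1))
  g2 <- mk_grid(matrix(c(2, 3, 7), 1))
  expect_equal(as.vector(minmax_normalize(g2)$values), c(0, 0.2, 1))
  # exact endpoint property on random grids
  set.seed(11)
  for (i in 1:5) {
    g3 <- mk_grid(matrix(rnorm(48), 6, 8))
    out <- minmax_normalize(g3)$values
    expect_identical(min(out), 0)
    expect_identical(max(out), 1)
  }
})

test_that("min-max normalisation honours the study-area mask", {
  v <- matrix(seq(0, 1.5, length.out = 16), 4, 4)
  g <- mk_grid(v)
  mask <- matrix(FALSE, 4, 4); mask[2:3, 2:3] <- TRUE
  out <- minmax_normalize(g, mask = mask)
  expect_equal(min(out$values[mask]), 0)
  expect_equal(max(out$values[mask]), 1)
  # out-of-mask cells rescaled with in-mask extrema (can exceed [0, 1])
  expect_true(any(out$values[!mask] < 0 | out$values[!mask] > 1))
  clipped <- minmax_normalize(g, mask = mask, clip_to_mask = TRUE)
  expect_true(all(is.na(clipped$values[!mask])))
})

test_that("degenerate normalisation is rejected", {
  expect_error(minmax_normalize(mk_grid(matrix(4, 3, 3))), "degenerate")
})

test_that("maximum composite ignores nodata and keeps all-nodata cells", {
  g1 <- mk_grid(matrix(c(0.2, NA), 1))
  g2 <- mk_grid(matrix(c(0.5, NA), 1))
  g3 <- mk_grid(matrix(c(0.3, -0.1), 1))
  out <- max_composite(list(g1, g2, g3))
  expect_equal(out$values[1, 1], 0.5)
  expect_equal(out$values[1, 2], -0.1)        # nodata skipped, not zeroed
  expect_true(is.na(max_composite(list(g1, g2))$values[1, 2]))
  expect_identical(max_composite(list(g1))$values, g1$values)
})

test_that("maximum composite is idempotent, commutative and associative", {
  set.seed(3)
  gs <- lapply(1:3, function(i) mk_grid(matrix(rnorm(20), 4, 5)))
  ab <- max_composite(gs[1:2])$values
  ba <- max_composite(gs[2:1])$values
  expect_identical(ab, ba)
  left <- max_composite(list(max_composite(gs[1:2]), gs[[3]]))$values
  right <- max_composite(list(gs[[1]], max_composite(gs[2:3])))$values
  expect_identical(left, right)
  expect_identical(max_composite(list(gs[[1]], gs[[1]]))$values,
                   gs[[1]]$values)
})

test_that("misaligned composite inputs are rejected with the failing attribute", {
  g1 <- mk_grid(matrix(0, 2, 2))
  g2 <- mk_grid(matrix(0, 2, 3))
  expect_error(max_composite(list(g1, g2)), "shape")
  g3 <- rn_grid(matrix(0, 2, 2), y0 = 200, cell = 50)
  expect_error(max_composite(list(g1, g3)), "cell size")
  g4 <- rn_grid(matrix(0, 2, 2), x0 = 30, cell = 100)
  expect_error(max_composite(list(g1, g4)), "origin")
})

test_that("bilinear resampling is the identity on the source spec", {
  set.seed(5)
  g <- mk_grid(matrix(rnorm(30), 5, 6))
  out <- resample_bilinear(g, grid_spec_of(g))
  expect_equal(out$values, g$values)
})

test_that("bilinear resampling reproduces affine surfaces exactly", {
  spec <- mk_spec(20, 20, cell = 100)
  ctr <- cell_centres(spec)
  ramp <- outer(ctr$y, ctr$x, function(y, x) 3 + 0.002 * x + 0.005 * y)
  g <- grid_from_spec(spec, ramp)
  for (cellsize in c(50, 200, 130)) {
    tgt <- rn_grid_spec(ceiling(2000 / cellsize) - 1,
                        ceiling(2000 / cellsize) - 1,
                        x0 = 100, y0 = 1900, cell = cellsize)
    out <- resample_bilinear(g, tgt)
    tc <- cell_centres(tgt)
    want <- outer(tc$y, tc$x, function(y, x) 3 + 0.002 * x + 0.005 * y)
    ok <- !is.na(out$values)
    expect_gt(mean(ok), 0.8)
    expect_lt(max(abs(out$values[ok] - want[ok])), 1e-9)
  }
  # constant grids stay constant
  cg <- grid_from_spec(spec, 7)
  out <- resample_bilinear(cg, rn_grid_spec(9, 9, x0 = 100, y0 = 1900,
                                            cell = 200))
  expect_true(all(out$values[!is.na(out$values)] == 7))
})

test_that("nodata within the interpolation support poisons the output cell", {
  v <- matrix(1, 4, 4); v[2, 2] <- NA
  g <- mk_grid(v, cell = 100)
  tgt <- rn_grid_spec(3, 3, x0 = 50, y0 = 350, cell = 100)
  out <- resample_bilinear(g, tgt)
  expect_true(is.na(out$values[1, 1]))        # support includes the NA cell
  expect_equal(out$values[3, 3], 1)
})

test_that("resampling rejects CRS mismatch and extreme scale ratios", {
  g <- mk_grid(matrix(0, 4, 4), crs = "EPSG:32650")
  expect_error(resample_bilinear(g, mk_spec(4, 4, crs = "EPSG:32651")),
               "CRS mismatch")
  expect_error(resample_bilinear(mk_grid(matrix(0, 4, 4)),
                                 mk_spec(2, 2, cell = 1500)),
               "within")
})

test_that("align_stack puts mixed-resolution grids on the common grid", {
  target <- mk_spec(10, 10, cell = 100)
  make_at <- function(cell) {
    n <- floor(1000 / cell)
    spec <- rn_grid_spec(n, n, x0 = 0, y0 = 1000, cell = cell)
    ctr <- cell_centres(spec)
    grid_from_spec(spec, outer(ctr$y, ctr$x, function(y, x) x + 2 * y))
  }
  out <- align_stack(list(make_at(130), make_at(250)), target)
  expect_true(grids_aligned(out[[1]], out[[2]]))
  expect_identical(dim(out[[1]]$values), c(10L, 10L))
  tc <- cell_centres(target)
  want <- outer(tc$y, tc$x, function(y, x) x + 2 * y)
  ok <- !is.na(out[[1]]$values)
  expect_lt(max(abs(out[[1]]$values[ok] - want[ok])), 1e-9)
})
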