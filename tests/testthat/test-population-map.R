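test_that("zonal sums match an exhaustive point-in-polygon oracle", {
  set.seed(41)
  spec <- mk_spec(20, 20, cell = 100)
  g <- grid_from_spec(spec, matrix(runif(400), 20, 20))
  zones <- toy_zones()
  got <- zonal_sum(g, zones)
  # brute force: test every cell centre against every ring
  ctr <- cell_centres(spec)
  want <- stats::setNames(numeric(4), zones$zone_id)
  for (r in 1:20) for (c in 1:20) {
    for (zi in seq_len(n_zones(zones))) {
      if (oracle_point_in_ring(zones$polygons[[zi]][[1]],
                               ctr$x[c], ctr$y[r])) {
        want[zi] <- want[zi] + g$values[r, c]
        break
      }
    }
  }
  expect_equal(got, want, tolerance = 1e-12)
  # the four zones partition the grid: sums add to the grid total
  expect_equal(sum(got), sum(g$values), tolerance = 1e-12)
})

test_that("zonal sums handle constants, whole-grid zones and empty zones", {
  spec <- mk_spec(10, 10, cell = 100)
  g <- grid_from_spec(spec, 3)
  whole <- zone_set("all", list(list(rbind(c(0, 0), c(1000, 0),
                                           c(1000, 1000), c(0, 1000)))),
                    population = 10)
  expect_equal(unname(zonal_sum(g, whole)), 300)
  quarter <- zone_set("q", list(list(rbind(c(0, 0), c(500, 0),
                                           c(500, 500), c(0, 500)))),
                      population = 10)
  expect_equal(unname(zonal_sum(g, quarter)), 25 * 3)
  tiny <- zone_set("t", list(list(rbind(c(10, 10), c(20, 10),
                                        c(20, 20), c(10, 20)))),
                   population = 0)
  expect_warning(s <- zonal_sum(g, tiny), "no cell centres")
  expect_equal(unname(s), 0)
})

test_that("linear calibration matches the normal-equations oracle", {
  fit <- fit_linear_calibration(c(1, 2, 3), c(2, 4, 6))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  # constant response: flat line, perfect fit
  fit2 <- fit_linear_calibration(c(1, 2, 3), c(5, 5, 5))
  expect_equal(fit2$slope, 0, tolerance = 1e-12)
  expect_equal(fit2$intercept, 5, tolerance = 1e-12)
  expect_equal(fit2$r_squared, 1)
  expect_error(fit_linear_calibration(c(2, 2, 2), c(1, 2, 3)), "degenerate")
  # noisy 10-zone fixture vs closed-form OLS
  set.seed(51)
  x <- runif(10, 0, 100); y <- 3 * x + 40 + rnorm(10, 0, 5)
  got <- fit_linear_calibration(x, y)
  sxy <- sum((x - mean(x)) * (y - mean(y))); sxx <- sum((x - mean(x))^2)
  expect_equal(got$slope, sxy / sxx, tolerance = 1e-12)
  expect_equal(got$intercept, mean(y) - sxy / sxx * mean(x),
               tolerance = 1e-12)
})

test_that("correction factor is the actual-to-estimated ratio", {
  expect_equal(correction_factor(100, 100), 1)
  expect_equal(correction_factor(100, 82), 0.82)
  expect_equal(correction_factor(400, 500), 1.25)
  expect_error(correction_factor(0, 10), "positive")
})

test_that("proportional disaggregation splits counts by index share", {
  spec <- mk_spec(2, 2, cell = 100)
  zones <- zone_set("z", list(list(rbind(c(0, 0), c(200, 0),
                                         c(200, 200), c(0, 200)))),
                    population = 100)
  uni <- disaggregate(grid_from_spec(spec, 1), zones, mode = "proportional")
  expect_true(all(uni$values == 25))
  g <- grid_from_spec(mk_spec(1, 2, cell = 100),
                      matrix(c(1, 3), 1))
  z2 <- zone_set("z", list(list(rbind(c(0, 0), c(200, 0),
                                      c(200, 100), c(0, 100)))),
                 population = 80)
  out <- disaggregate(g, z2, mode = "proportional")
  expect_equal(as.vector(out$values), c(20, 60))
})

test_that("every mode conserves the census total; by-zone conserves per zone", {
  set.seed(61)
  spec <- mk_spec(20, 20, cell = 100)
  idx <- grid_from_spec(spec, matrix(rexp(400), 20, 20))
  zones <- toy_zones(pop = c(120, 3400, 550, 980))
  assign <- zone_assignment(zones, spec)
  fit <- fit_linear_calibration(zonal_sum(idx, zones, assignment = assign),
                                zones$population)
  total <- sum(zones$population)
  for (mode in c("regression", "proportional", "proportional_by_zone")) {
    pop <- disaggregate(idx, zones, fit = fit, mode = mode,
                        assignment = assign)
    expect_lt(abs(sum(pop$values, na.rm = TRUE) - total) / total, 1e-9)
    expect_true(all(pop$values >= 0, na.rm = TRUE))
  }
  byz <- disaggregate(idx, zones, mode = "proportional_by_zone",
                      assignment = assign)
  expect_equal(zonal_sum(byz, zones, assignment = assign),
               stats::setNames(zones$population, zones$zone_id),
               tolerance = 1e-12)
})

test_that("proportional modes are invariant to uniform index rescaling", {
  set.seed(62)
  spec <- mk_spec(10, 10, cell = 100)
  idx <- grid_from_spec(spec, matrix(runif(100), 10, 10))
  zones <- toy_zones(pop = c(10, 20, 30, 40))
  zones$polygons <- lapply(zones$polygons, function(p)
    lapply(p, function(r) r / 2))  # shrink to cover the 10x10 grid
  zones <- zone_set(zones$zone_id, zones$polygons, zones$population)
  for (mode in c("proportional", "proportional_by_zone")) {
    a <- disaggregate(idx, zones, mode = mode)
    idx2 <- idx; idx2$values <- idx$values * 37.5
    b <- disaggregate(idx2, zones, mode = mode)
    expect_equal(a$values, b$values, tolerance = 1e-12)
  }
})

test_that("a zero-index zone with census is spread uniformly with a warning", {
  spec <- mk_spec(10, 10, cell = 100)
  v <- matrix(1, 10, 10); v[1:5, 1:5] <- 0   # zone c (top-left) all zero
  idx <- grid_from_spec(spec, v)
  zones <- toy_zones(pop = c(10, 20, 40, 40))
  zones$polygons <- lapply(zones$polygons, function(p)
    lapply(p, function(r) r / 2))
  zones <- zone_set(zones$zone_id, zones$polygons, zones$population)
  expect_warning(out <- disaggregate(idx, zones,
                                     mode = "proportional_by_zone"),
                 "zero index")
  expect_true(all(abs(out$values[1:5, 1:5] - 40 / 25) < 1e-12))
})

test_that("density conversion is per 0.01 km^2", {
  g100 <- rn_grid(matrix(37, 1), cell = 100)
  expect_equal(to_density(g100)$values[1, 1], 37)      # identity at 100 m
  g200 <- rn_grid(matrix(40, 1), cell = 200)
  expect_equal(to_density(g200)$values[1, 1], 10)      # area ratio 4
  expect_equal(to_density(rn_grid(matrix(0, 1), cell = 100))$values[1, 1], 0)
})
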