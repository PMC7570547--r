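test_that("line density matches the brute-force quadrature oracle", {
  spec <- mk_spec(40, 40, cell = 100)
  h <- 500                                     # 5 cells
  net <- toy_network()
  # fine sampling on both sides: implementation at spacing h/2000,
  # oracle at quadrature step h/1e4
  impl <- line_kde(net, NULL, h, spec,
                   spacing_factor = (h / 2000) / spec$cell)
  want <- oracle_line_kde(net$lines, h, spec)
  expect_lt(max(abs(impl$values - want)) / max(want), 1e-6)
})

test_that("density has compact support and is additive over features", {
  spec <- mk_spec(40, 40, cell = 100)
  h <- 500
  one <- road_network(list(rbind(c(1950, 2000), c(2050, 2000))), "trunk")
  g <- line_kde(one, "trunk", h, spec)
  expect_true(all(g$values >= 0))
  # cells farther than h from every point of the segment are exactly zero
  ctr <- cell_centres(spec)
  dist_to_seg <- function(x, y) {
    t <- pmin(pmax((x - 1950) / 100, 0), 1)
    sqrt((x - (1950 + 100 * t))^2 + (y - 2000)^2)
  }
  d <- outer(ctr$y, ctr$x, function(y, x) dist_to_seg(x, y))
  expect_true(all(g$values[d > h + 1e-9] == 0))
  expect_true(any(g$values[d < h - 50] > 0))
  # additivity: KDE(A union B) = KDE(A) + KDE(B) exactly
  a <- road_network(list(rbind(c(1200, 2000), c(2800, 2000))), "trunk")
  b <- road_network(list(rbind(c(2000, 1200), c(2000, 2800))), "trunk")
  both <- road_network(c(a$lines, b$lines), c("trunk", "trunk"))
  expect_equal(line_kde(both, "trunk", h, spec)$values,
               line_kde(a, "trunk", h, spec)$values +
                 line_kde(b, "trunk", h, spec)$values,
               tolerance = 1e-14)
})

test_that("grid total conserves line length away from edges", {
  spec <- mk_spec(60, 60, cell = 100)
  h <- 800
  net <- road_network(
    list(rbind(c(1500, 3000), c(4500, 3200)),
         rbind(c(3000, 1500), c(2800, 4500)),
         rbind(c(2000, 2000), c(4000, 4000))),
    rep("branch", 3))
  g <- line_kde(net, "branch", h, spec)
  mass <- sum(g$values) * spec$cell^2
  expect_lt(abs(mass - network_length(net)) / network_length(net), 0.01)
})

test_that("a class with no features yields a zero grid with a warning", {
  spec <- mk_spec(10, 10)
  net <- toy_network()
  expect_warning(g <- line_kde(net, "railway", 500, spec), "railway")
  expect_true(all(g$values == 0))
})

test_that("bandwidth sweep reports Pearson r per class and bandwidth", {
  spec <- mk_spec(20, 20, cell = 100)
  net <- toy_network()
  zones <- toy_zones()
  # reference correlations computed directly from zonal sums
  assign <- zone_assignment(zones, spec)
  for (bw in c(300, 600)) {
    for (cl in c("trunk", "branch")) {
      zs <- zonal_sum(line_kde(net, cl, bw, spec), zones,
                      assignment = assign)
      sw <- bandwidth_sweep(net, zones, c(300, 600), spec)
      bi <- match(bw, sw$bandwidths)
      # textbook Pearson formula as the oracle
      x <- zs; y <- zones$population
      r_hand <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      expect_equal(unname(sw$r[bi, cl]), r_hand, tolerance = 1e-12)
    }
  }
})

test_that("sweep selects the configured default or the mean-r maximiser", {
  spec <- mk_spec(20, 20, cell = 100)
  net <- toy_network()
  # census proportional to the zonal density sums at 600 m: r = 1 there
  zs <- zonal_sum(line_kde(net, NULL, 600, spec), toy_zones())
  zones <- toy_zones(pop = round(1e5 * zs / max(zs)) + 1)
  sw <- bandwidth_sweep(net, zones, c(300, 600), spec,
                        default_bandwidth = 3000)
  expect_identical(sw$chosen, 3000)
  sw2 <- bandwidth_sweep(net, zones, c(300, 600), spec,
                         choose = "max_mean_r")
  expect_true(sw2$chosen %in% c(300, 600))
  expect_true(all(sw$r >= -1 & sw$r <= 1, na.rm = TRUE))
  tab <- sweep_table(sw)
  expect_identical(nrow(tab), length(sw$bandwidths) * ncol(sw$r))
})

test_that("PCA weights: symmetric cases and eigen oracle agreement", {
  set.seed(21)
  # two perfectly correlated classes split the weight evenly
  x <- cbind(trunk = rnorm(12), branch = 0)
  x[, "branch"] <- 3 * x[, "trunk"] + 5
  w <- pca_class_weights(x)
  expect_equal(unname(w$weights), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sum(w$weights), 1, tolerance = 1e-9)

  # 10 x 3 fixture against an independent eigendecomposition oracle
  m <- cbind(a = rnorm(10, 5), b = rnorm(10, 2), c = runif(10, 0, 9))
  got <- pca_class_weights(m)
  e <- eigen(stats::cor(m), symmetric = TRUE)
  keep <- which(e$values >= 1 - 1e-9)
  prop <- e$values / sum(e$values)
  raw <- abs(e$vectors[, keep, drop = FALSE]) %*% prop[keep]
  expect_equal(unname(got$weights), as.vector(raw / sum(raw)),
               tolerance = 1e-9)
})

test_that("PCA weights are invariant to column rescaling and ordering", {
  set.seed(22)
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(NULL, c("w", "x", "y", "z")))
  w1 <- pca_class_weights(m)$weights
  scaled <- sweep(m, 2, c(10, 0.01, 3, 1000), `*`)
  expect_equal(pca_class_weights(scaled)$weights, w1, tolerance = 1e-9)
  perm <- m[, c(3, 1, 4, 2)]
  w2 <- pca_class_weights(perm)$weights
  expect_equal(w2[names(w1)], w1, tolerance = 1e-9)
})

test_that("PCA weight preconditions are enforced", {
  expect_error(pca_class_weights(cbind(a = 1:5)), "two road classes")
  expect_error(pca_class_weights(matrix(rnorm(6), 2, 3,
                                        dimnames = list(NULL, letters[1:3]))),
               "more zones")
  m <- cbind(a = rnorm(8), b = rep(2, 8))
  expect_error(pca_class_weights(m), "b")
})

test_that("composite overlays class densities with their weights", {
  spec <- mk_spec(3, 3)
  mk <- function(v) grid_from_spec(spec, v)
  # single class, weight 1: identity
  g <- mk(matrix(runif(9), 3, 3))
  expect_identical(composite_rnd(list(trunk = g), c(trunk = 1))$values,
                   g$values)
  # two classes at (0.5, 0.5): per-cell mean
  g2 <- mk(matrix(runif(9), 3, 3))
  out <- composite_rnd(list(trunk = g, branch = g2),
                       c(trunk = 0.5, branch = 0.5))
  expect_equal(out$values, (g$values + g2$values) / 2)
  # six constant layers under the six-class weight vector: hand-computed sum
  weights <- c(expressway = 0.2, trunk = 0.15, secondary_trunk = 0.08,
               branch = 0.15, railway = 0.21, other = 0.2)
  grids <- Map(function(v) mk(matrix(v, 3, 3)), as.list(1:6))
  names(grids) <- names(weights)
  out6 <- composite_rnd(grids, weights)
  expect_equal(out6$values[2, 2],
               0.2 * 1 + 0.15 * 2 + 0.08 * 3 + 0.15 * 4 + 0.21 * 5 + 0.2 * 6)
  # class/weight mismatch rejected
  expect_error(composite_rnd(list(trunk = g), c(branch = 1)), "mismatch")
})
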