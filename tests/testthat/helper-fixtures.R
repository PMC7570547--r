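# Shared fixtures and independent oracles. Oracles here are deliberately
# naive (quadrature, exhaustive containment, eigen-by-hand) and never call
# the package code paths they check.

mk_grid <- function(values, cell = 100, x0 = 0, crs = "local-metres") {
  rn_grid(values, x0 = x0, cell = cell, crs = crs)
}

mk_spec <- function(nr, nc, cell = 100, x0 = 0, crs = "local-metres") {
  rn_grid_spec(nr, nc, x0 = x0, cell = cell, crs = crs)
}

# Brute-force line KDE: fine midpoint quadrature of the kernel line integral
# along every segment, evaluated at every cell centre. step defaults to the
# h/1e4 quadrature used for oracle comparisons. Chunked outer products keep
# memory bounded.
oracle_line_kde <- function(lines, h, spec, step = h / 1e4) {
  ctr <- cell_centres(spec)
  X <- rep(ctr$x, each = spec$nrow)   # column-major cell coordinates
  Y <- rep(ctr$y, times = spec$ncol)
  out <- numeric(spec$nrow * spec$ncol)
  norm <- 3 / (pi * h^2)
  for (m in lines) {
    for (s in seq_len(nrow(m) - 1L)) {
      p0 <- m[s, ]; p1 <- m[s + 1L, ]
      L <- sqrt(sum((p1 - p0)^2))
      if (L == 0) next
      n <- max(1L, ceiling(L / step))
      t <- (seq_len(n) - 0.5) / n
      qx <- p0[1L] + t * (p1[1L] - p0[1L])
      qy <- p0[2L] + t * (p1[2L] - p0[2L])
      w <- L / n
      for (lo in seq(1L, n, by = 2000L)) {
        hi <- min(lo + 1999L, n)
        u2 <- (outer(X, qx[lo:hi], "-")^2 +
                 outer(Y, qy[lo:hi], "-")^2) / h^2
        k <- (1 - u2)^2
        k[u2 >= 1] <- 0
        out <- out + w * norm * rowSums(k)
      }
    }
  }
  matrix(out, spec$nrow, spec$ncol)
}

# Ray-crossing point-in-polygon (single closed ring), the containment oracle.
oracle_point_in_ring <- function(ring, x, y) {
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  inside <- FALSE
  n <- nrow(ring)
  j <- n - 1L
  for (i in seq_len(n - 1L)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > y) != (yj > y) &&
        x < (xj - xi) * (y - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# A small deterministic road network for KDE tests: a handful of segments
# well inside an n x n grid.
toy_network <- function(cell = 100, crs = "local-metres") {
  lines <- list(
    rbind(c(1200, 2000), c(2800, 2000)),                    # horizontal
    rbind(c(2000, 1200), c(2000, 2800)),                    # vertical
    rbind(c(1300, 1300), c(2000, 2100), c(2700, 1500)))     # bent
  road_network(lines, c("trunk", "trunk", "branch"), crs = crs)
}

# Four rectangular zones tiling a 20 x 20 grid at 100 m.
toy_zones <- function(pop = c(100, 200, 300, 400), crs = "local-metres") {
  rect <- function(x0, y0, x1, y1)
    list(rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0)))
  zone_set(c("a", "b", "c", "d"),
           list(rect(0, 0, 1000, 1000), rect(1000, 0, 2000, 1000),
                rect(0, 1000, 1000, 2000), rect(1000, 1000, 2000, 2000)),
           population = pop, crs = crs)
}

# Small scene for fast end-to-end tests.
small_scene_params <- function(seed = 1L, ...) {
  scene_params(grid = rn_grid_spec(80, 80, cell = 100),
               n_centres = 3, centre_scale = 1500,
               roads_per_class = 4, n_zones = 16, n_evi = 5,
               kde_bandwidth = 2000, seed = seed, ...)
}
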