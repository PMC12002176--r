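test_that("polygon area and centroid have their closed-form values on squares", {
  sq <- gc_region(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(region_area(sq), 1.0)
  rev_sq <- gc_region(rev(c(0, 1, 1, 0)), rev(c(0, 0, 1, 1)))
  expect_equal(region_area(rev_sq), 1.0)
  expect_equal(unname(region_centroid(sq)), c(0.5, 0.5))

  shifted <- gc_region(c(0, 1, 1, 0) + 10, c(0, 0, 1, 1) - 3)
  expect_equal(unname(region_centroid(shifted)), c(10.5, -2.5))

  expect_error(gc_region(c(0, 1, 2), c(0, 1, 2)), "zero area")
  expect_error(gc_region(c(0, 1, 1, 0), c(0, 1, 0, 1)), "self-intersecting")
})

test_that("area matches a Monte-Carlo oracle and centroid a rasterization oracle", {
  set.seed(42)
  for (i in 1:8) {
    poly <- random_polygon(scale = runif(1, 0.5, 20), center = runif(2, -5, 5))
    expect_lt(abs(region_area(poly) - mc_area(poly)) / region_area(poly), 0.01)
  }
  # L-shaped polygon against pixel averaging
  L <- gc_region(c(0, 2, 2, 1, 1, 0), c(0, 0, 1, 1, 3, 3))
  expect_lt(sqrt(sum((region_centroid(L) - raster_centroid(L, grid = 1000))^2)),
            0.005 * bbox_diag(L))
})

test_that("polarization fraction reproduces hand-computed analytic cases", {
  sq <- square_region(10)
  even <- spatial_sample("g1", sq, data.frame(
    x = c(2, 2, -1, -1), y = c(1, -1, 1, -1), cell_type = "Tfh"))
  expect_equal(polarization_fraction(even, "Tfh")$fraction, 0.5)

  onesided <- spatial_sample("g2", sq, data.frame(
    x = c(5, 6, 5, 6), y = c(0, 0, 1, 1), cell_type = "Tfh"))
  expect_equal(polarization_fraction(onesided, "Tfh")$fraction, 1.0)

  expect_error(polarization_fraction(even, "FDC"), "unknown cell_type")
})

test_that("degenerate configurations report 0.5 with a flag", {
  sq <- square_region(1)
  one <- spatial_sample("g", sq, data.frame(x = 0.3, y = 0.1, cell_type = "a"))
  r1 <- polarization_fraction(one, "a")
  expect_true(r1$degenerate)
  expect_equal(r1$fraction, 0.5)

  # cell centroid exactly on the region centroid
  sym <- spatial_sample("g", sq, data.frame(
    x = c(-0.5, 0.5), y = c(0, 0), cell_type = "a"))
  r2 <- polarization_fraction(sym, "a")
  expect_true(r2$degenerate)
  expect_equal(r2$fraction, 0.5)
})

test_that("boundary cells within the tolerance split half to each side", {
  sq <- square_region(10)
  # direction is +x; one cell sits exactly on the splitting line
  s <- spatial_sample("g", sq, data.frame(
    x = c(3, 3, 0), y = c(1, -1, 0), cell_type = "a"))
  res <- polarization_fraction(s, "a", tol = 1e-9)
  expect_equal(res$fraction, (2 + 0.5) / 3)
})

test_that("fraction is rigid-motion invariant and confined to [0.5, 1]", {
  set.seed(7)
  n_sets <- 250
  for (i in seq_len(n_sets)) {
    poly <- random_polygon(scale = 5)
    n <- sample(2:80, 1)
    xy <- cbind(runif(n, -4, 4), runif(n, -4, 4))
    s <- spatial_sample("g", poly, data.frame(x = xy[, 1], y = xy[, 2], cell_type = "a"))
    f <- polarization_fraction(s, "a")$fraction
    expect_gte(f, 0.5)
    expect_lte(f, 1.0)
    expect_equal(f, polarization_oracle(poly, xy))

    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    shift <- runif(2, -50, 50)
    rxy <- sweep(xy %*% t(R), 2, shift, "+")
    rpoly <- gc_region(sweep(poly$xy %*% t(R), 2, shift, "+"))
    rs <- spatial_sample("g", rpoly, data.frame(x = rxy[, 1], y = rxy[, 2], cell_type = "a"))
    expect_equal(polarization_fraction(rs, "a")$fraction, f, tolerance = 1e-9)
  }
})

test_that("a one-sided cluster forces fraction exactly 1", {
  set.seed(8)
  for (i in 1:20) {
    poly <- random_polygon(scale = 10)
    cen <- region_centroid(poly)
    # cluster of radius r centered at distance > r from the centroid
    r <- runif(1, 0.5, 2)
    dist <- r + runif(1, 0.5, 3)
    th <- runif(1, 0, 2 * pi)
    ctr <- cen + dist * c(cos(th), sin(th))
    n <- sample(3:40, 1)
    u <- sqrt(runif(n, 0, r^2)); a <- runif(n, 0, 2 * pi)
    xy <- cbind(ctr[1] + u * cos(a), ctr[2] + u * sin(a))
    s <- spatial_sample("g", poly, data.frame(x = xy[, 1], y = xy[, 2], cell_type = "a"))
    expect_equal(polarization_fraction(s, "a")$fraction, 1.0)
  }
})

test_that("uniform cells are nearly unpolarized, more so with more cells", {
  disk <- local({
    ang <- seq(0, 2 * pi, length.out = 65)[-65]
    gc_region(cos(ang), sin(ang))
  })
  mean_frac <- function(n, reps, seed) {
    set.seed(seed)
    mean(vapply(seq_len(reps), function(i) {
      u <- sqrt(runif(n)); a <- runif(n, 0, 2 * pi)
      s <- spatial_sample("g", disk, data.frame(
        x = u * cos(a), y = u * sin(a), cell_type = "c"))
      polarization_fraction(s, "c")$fraction
    }, numeric(1)))
  }
  m100 <- mean_frac(100, 1000, seed = 9)
  expect_gte(m100, 0.5)
  expect_lte(m100, 0.56)
  m400 <- mean_frac(400, 300, seed = 10)
  expect_lt(m400, m100)
})

test_that("cell density is count over area and scales with coordinates", {
  sq <- square_region(5)  # area 100
  cells <- data.frame(x = runif(10, -5, 5), y = runif(10, -5, 5),
                      cell_type = rep(c("GCB", "FDC"), each = 5))
  s <- spatial_sample("g", sq, cells)
  d <- cell_density(s, "GCB")
  expect_equal(d$area, 100)
  expect_equal(d$density, 5 / 100)
  expect_equal(cell_density(s, "Tfh")$density, 0)  # absent type: zero density

  doubled <- spatial_sample("g", gc_region(2 * sq$xy),
                            transform(cells, x = 2 * x, y = 2 * y))
  expect_equal(cell_density(doubled, "GCB")$density, d$density / 4)

  # clipping drops cells outside the polygon
  out <- spatial_sample("g", sq, rbind(cells, data.frame(
    x = 50, y = 50, cell_type = "GCB")))
  expect_equal(cell_density(out, "GCB", clip = FALSE)$n_cells, 6)
  expect_equal(cell_density(out, "GCB", clip = TRUE)$n_cells, 5)
})

test_that("per-GC summaries combine density and polarization by type", {
  sq <- square_region(10)
  cells <- data.frame(x = c(5, 6, 5, 6, -2), y = c(0, 0, 1, 1, 3),
                      cell_type = c(rep("Tfh", 4), "FDC"))
  s <- spatial_sample("gc7", sq, cells)
  summ <- spatial_summary(s)
  expect_equal(nrow(summ), 2)
  expect_equal(summ$gc_id, rep("gc7", 2))
  tfh <- summ[summ$cell_type == "Tfh", ]
  expect_equal(tfh$fraction, 1.0)
  expect_equal(tfh$density, 4 / 400)
  expect_true(summ$degenerate[summ$cell_type == "FDC"])
})
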