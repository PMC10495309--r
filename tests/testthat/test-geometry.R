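test_that("cells_per_axis reproduces the published per-axis counts", {
  expect_identical(cells_per_axis(140, 4.65, 10), 15L)
  expect_identical(cells_per_axis(86.53, 4.65, 5), 19L)
  expect_identical(cells_per_axis(280, 4.65, 40), 9L)
  # range smaller than one cell pitch: only the central cell remains
  expect_identical(cells_per_axis(1, 4.65, 10), 1L)
  expect_error(cells_per_axis(-1, 4.65, 10), "positive")
  expect_error(cells_per_axis(140, 0, 10), "positive")
})

test_that("cells_per_axis is odd and monotone in range and half-length", {
  ranges <- c(5, 20, 86.53, 140, 280, 500)
  hls <- c(2, 5, 8, 10, 12.5, 14.142, 20, 40)
  for (hl in hls) {
    n <- vapply(ranges, cells_per_axis, integer(1),
                nucleus_radius = 4.65, half_length = hl)
    expect_true(all(n %% 2L == 1L))
    expect_true(all(diff(n) >= 0))
  }
  for (r in ranges) {
    n <- vapply(hls, function(h) cells_per_axis(r, 4.65, h), integer(1))
    expect_true(all(diff(n) <= 0))
  }
})

test_that("the five catalog geometries are equal-volume ellipsoids", {
  tab <- cell_geometry()
  expect_identical(nrow(tab), 5L)
  vols <- vapply(1:5, function(i) cell_volume(cell_geometry(i)), numeric(1))
  expect_true(all(abs(vols - 4188.79) / 4188.79 < 0.005))
})

test_that("clusters reproduce all twenty published cell totals", {
  expected <- rbind(
    lu_2d = c(841, 667, 435, 513, 441),
    lu_3d = c(3375, 3705, 3915, 4205, 3509),
    ac_2d = c(121, 99, 55, 57, 49),
    ac_3d = c(1331, 1287, 1045, 1083, 931))
  got <- sapply(1:5, function(g) {
    cell <- cell_geometry(g)
    c(build_cluster(cell, "planar_2d", "Lu177")$n_cells,
      build_cluster(cell, "lattice_3d", "Lu177")$n_cells,
      build_cluster(cell, "planar_2d", "Ac225")$n_cells,
      build_cluster(cell, "lattice_3d", "Ac225")$n_cells)
  })
  expect_equal(unname(got), unname(expected), ignore_attr = TRUE)
})

test_that("planar clusters span the two longest axes and tile without overlap", {
  # geometry 4 (5, 40, 5): monolayer in the HL=40 / HL=5 plane
  cl <- build_cluster(cell_geometry(4), "planar_2d", "Ac225")
  expect_identical(sort(cl$counts_per_axis), c(1L, 3L, 19L))
  expect_identical(cl$counts_per_axis[2], 3L)  # HL = 40 axis
  expect_identical(cl$n_cells, 57L)
  # pitch is 2*HL per axis and the central cell sits at the origin
  lay <- cluster_layout(cl)
  expect_true(any(lay$ix == 0 & lay$iy == 0 & lay$iz == 0))
  expect_equal(sort(unique(lay$x_um)), 2 * 5 * sort(unique(lay$ix)))
  expect_equal(sort(unique(lay$y_um)), 2 * 40 * sort(unique(lay$iy)))
  expect_false(any(duplicated(lay[, c("ix", "iy", "iz")])))
})

test_that("point_region classifies nucleus, cytoplasm, membrane, outside", {
  g1 <- cell_geometry(1)
  expect_identical(point_region(g1, c(0, 0, 0)), "nucleus")
  expect_identical(point_region(g1, c(9.999, 0, 0)), "membrane")
  expect_identical(point_region(g1, c(7, 0, 0)), "cytoplasm")
  expect_identical(point_region(cell_geometry(4), c(0, 41, 0)), "outside")
  # exhaustive and mutually exclusive on a random cloud
  set.seed(1)
  p <- matrix(runif(3000, -11, 11), ncol = 3)
  expect_true(all(point_region(g1, p) %in%
                    c("nucleus", "cytoplasm", "membrane", "outside")))
})

test_that("sphere surface sampling is exactly on-surface and cap-uniform", {
  sphere <- ellipsoid_cell(c(10, 10, 10))
  p <- sample_source_positions(sphere, "membrane_bound", 1e5, rng_seed = 11)
  r <- sqrt(rowSums(p^2))
  expect_lt(max(abs(r - 10)), 1e-3)
  expect_lt(abs(mean(r) - 10), 1e-3)
  # equal-area z-bands must be equally occupied (z is uniform on a sphere)
  counts <- table(cut(p[, 3], breaks = seq(-10, 10, length.out = 21)))
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 1e-4)
})

test_that("ellipsoid surface sampling matches a triangulation oracle", {
  hl <- cell_geometry(2)$half_lengths
  n <- 2e4
  p <- sample_source_positions(cell_geometry(2), "membrane_bound", n,
                               rng_seed = 21)
  set.seed(22)
  q <- oracle_ellipsoid_surface(hl, n)
  for (j in 1:3) {
    ks <- suppressWarnings(stats::ks.test(p[, j], q[, j]))
    expect_lt(unname(ks$statistic), 0.02)
  }
})

test_that("cytoplasm sampling is volume-uniform and avoids the nucleus", {
  g2 <- cell_geometry(2)
  n <- 1e5
  p <- sample_source_positions(g2, "internalized", n, rng_seed = 31)
  r <- sqrt(rowSums(p^2))
  expect_true(all(r > g2$nucleus_radius))
  expect_true(all(point_region(g2, p) == "cytoplasm"))
  # analytic volume fraction of the shell 4.65 < r < 6 um (the 6-um sphere
  # lies fully inside the inner ellipsoid)
  hin <- g2$half_lengths - g2$membrane_thickness
  v_cyt <- (4 / 3) * pi * (prod(hin) - g2$nucleus_radius^3)
  frac <- (4 / 3) * pi * (6^3 - g2$nucleus_radius^3) / v_cyt
  obs <- mean(r < 6)
  expect_lt(abs(obs - frac), 3 * sqrt(frac * (1 - frac) / n))
  # octant symmetry
  oct <- table(paste(sign(p[, 1]), sign(p[, 2]), sign(p[, 3])))
  expect_gt(stats::chisq.test(as.vector(oct))$p.value, 1e-4)
})

test_that("source-position sampling is reproducible and handles n = 0", {
  g1 <- cell_geometry(1)
  expect_identical(nrow(sample_source_positions(g1, "internalized", 0)), 0L)
  a <- sample_source_positions(g1, "membrane_bound", 50, rng_seed = 5)
  b <- sample_source_positions(g1, "membrane_bound", 50, rng_seed = 5)
  expect_identical(a, b)
  expect_error(sample_source_positions(g1, "internalized", -1), ">= 0")
})
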