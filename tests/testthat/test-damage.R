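test_that("the alpha range-energy law hits both printed CSDA anchors", {
  arm <- alpha_range_model()
  expect_equal(arm$range_of_energy(8.5), 86.53, tolerance = 1e-10)
  r58 <- arm$range_of_energy(5.8)
  expect_gte(r58, 43)
  expect_lte(r58, 49)
  # residual energy inverts the range law
  expect_equal(arm$residual_energy(8.4, 0), 8.4)
  expect_equal(arm$residual_energy(8.4, arm$range_of_energy(8.4)), 0)
})

test_that("chord_intersection solves the ray-sphere geometry", {
  # ray from the sphere center exits at R
  ch <- chord_intersection(c(0, 0, 0), c(1, 0, 0), radius = 4.65)
  expect_equal(unname(ch[1, ]), c(0, 4.65))
  # tangent ray: zero-length chord
  ch <- chord_intersection(c(0, 4.65, -10), c(0, 0, 1), radius = 4.65)
  expect_equal(unname(ch[1, 2] - ch[1, 1]), 0, tolerance = 1e-6)
  # miss, and sphere behind the origin
  expect_true(all(is.na(chord_intersection(c(0, 10, -10), c(0, 0, 1),
                                           radius = 4.65))))
  expect_true(all(is.na(chord_intersection(c(0, 0, 10), c(0, 0, 1),
                                           radius = 4.65))))
  expect_error(chord_intersection(c(0, 0, 10), c(0, 0, 0), radius = 4.65),
               "zero direction")
})

test_that("chords agree with a ray-march oracle from an exterior point", {
  set.seed(101)
  origin <- c(12, -5, 7)
  dirs <- matrix(rnorm(3 * 4000), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  ch <- chord_intersection(matrix(origin, 4000, 3, byrow = TRUE), dirs,
                           radius = 4.65)
  hit <- which(!is.na(ch[, 1]) & (ch[, 2] - ch[, 1]) > 0)
  hit <- hit[seq_len(min(100, length(hit)))]
  expect_gte(length(hit), 50)
  analytic <- mean(ch[hit, 2] - ch[hit, 1])
  marched <- mean(vapply(hit, function(i) {
    oracle_ray_march_chord(origin, dirs[i, ], 4.65)
  }, numeric(1)))
  expect_lt(abs(marched - analytic) / analytic, 0.001)
})

test_that("energy deposition converts to nucleus dose at 0.380 Gy/MeV", {
  expect_equal(energy_to_dose(1), 0.380, tolerance = 2e-3)
  expect_equal(energy_to_dose(0), 0)
})

test_that("an Ac-225 source at the nucleus center deposits the closed-form energy", {
  # all five chain alphas start at the center: chord is (0, 4.65) regardless
  # of direction, so the deposited energy is sum(E0 - E_res(E0, 4.65)),
  # hand-evaluated from the two-anchor power law as 1.65899 MeV
  cl <- build_cluster(cell_geometry(1), "lattice_3d", "Ac225")
  rec <- simulate_ac_run(cl, matrix(0, 1, 3), rng_seed = 1)
  expect_equal(rec$dose_Gy, 1.65899 * 0.380420, tolerance = 1e-4)
  expect_true(all(rec$dsbs$complexity == "complex"))
})

test_that("Ac-225 runs respect energy bookkeeping and nucleus confinement", {
  cl <- build_cluster(cell_geometry(1), "lattice_3d", "Ac225")
  src <- plan_sources(cl, "internalized", 2, rng_seed = 3)
  rec <- simulate_ac_run(cl, src, rng_seed = 4)
  # total deposited energy cannot exceed the emitted 33.5 MeV per source
  expect_lte(rec$dose_Gy, nrow(src) * 33.5 * 0.3805)
  if (nrow(rec$dsbs) > 0) {
    r <- sqrt(rec$dsbs$x^2 + rec$dsbs$y^2 + rec$dsbs$z^2)
    expect_true(all(r <= 4.65 + 1e-9))
  }
  # empty plan gives an empty record
  rec0 <- simulate_ac_run(cl, matrix(numeric(0), ncol = 3))
  expect_identical(rec0$dose_Gy, 0)
  expect_identical(nrow(rec0$dsbs), 0L)
  expect_error(simulate_ac_run(build_cluster(cell_geometry(1), "lattice_3d",
                                             "Lu177"), src),
               "not built for Ac225")
})

test_that("Lu-177 dose is linear in the source count and kernel-driven", {
  cl <- build_cluster(cell_geometry(1), "lattice_3d", "Lu177")
  quiet <- damage_params(lu_noise_rel_sd = 1e-4)
  d1 <- simulate_lu_run(cl, 500, "internalized", quiet, rng_seed = 7)
  d2 <- simulate_lu_run(cl, 1000, "internalized", quiet, rng_seed = 8)
  expect_equal(d2$dose_Gy / d1$dose_Gy, 2, tolerance = 1e-3)
  # DSBs inside the nucleus, Poisson count near yield * dose
  r <- sqrt(d2$dsbs$x^2 + d2$dsbs$y^2 + d2$dsbs$z^2)
  expect_true(all(r <= 4.65 + 1e-9))
  lambda <- 77 * d2$dose_Gy
  expect_lt(abs(nrow(d2$dsbs) - lambda), 5 * sqrt(lambda))
  expect_error(simulate_lu_run(build_cluster(cell_geometry(1), "lattice_3d",
                                             "Ac225"), 100, "internalized"),
               "not built for Lu177")
})

test_that("damage simulation is reproducible under a fixed seed", {
  cl <- build_cluster(cell_geometry(1), "lattice_3d", "Lu177")
  a <- simulate_lu_run(cl, 700, "internalized", rng_seed = 42)
  b <- simulate_lu_run(cl, 700, "internalized", rng_seed = 42)
  expect_equal(a$dose_Gy, b$dose_Gy)
  expect_equal(a$dsbs, b$dsbs)
  cla <- build_cluster(cell_geometry(2), "lattice_3d", "Ac225")
  src <- plan_sources(cla, "membrane_bound", 3, rng_seed = 9)
  x <- simulate_ac_run(cla, src, rng_seed = 10)
  y <- simulate_ac_run(cla, src, rng_seed = 10)
  expect_equal(x$dose_Gy, y$dose_Gy)
  expect_equal(x$dsbs, y$dsbs)
})

test_that("a fraction of Lu DSBs forms close doublets inside the nucleus", {
  cl <- build_cluster(cell_geometry(1), "planar_2d", "Lu177")
  rec <- simulate_lu_run(cl, 5000, "internalized", rng_seed = 12)
  pos <- as.matrix(rec$dsbs[, c("x", "y", "z")])
  nn <- apply(as.matrix(stats::dist(pos)) + diag(Inf, nrow(pos)), 1, min)
  # with a 0.30 doublet fraction, far more breaks have a sub-0.5-um
  # neighbour than uniform placement would give
  expect_gt(mean(nn < 0.5), 0.15)
  expect_true(all(sqrt(rowSums(pos^2)) <= 4.65 + 1e-9))
})
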