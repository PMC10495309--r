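test_that("empty damage repairs to an empty outcome", {
  out <- repair_run(make_damage(matrix(numeric(0), ncol = 3), character(0), 0))
  expect_identical(out$n_initial, 0L)
  expect_identical(out$n_post, 0L)
  mp <- mean_post_repair(make_damage(matrix(numeric(0), ncol = 3),
                                     character(0), 0))
  expect_equal(mp$mean, 0)
  expect_equal(mp$sd, 0)
})

test_that("an isolated simple break restitutes with near-certainty in 24 h", {
  # survival probability exp(-2.07 * 24) ~ 2.7e-22; misrepair is impossible
  dmg <- make_damage(matrix(c(0, 0, 0), 1, 3), "simple")
  rp <- repair_params(complex_unrepaired_prob = 0)
  for (s in 1:25) {
    out <- repair_run(dmg, rp, rng_seed = s)
    expect_identical(out$n_correct, 1L)
    expect_identical(out$n_misrepaired, 0L)
  }
})

test_that("widely separated breaks never misrepair as sigma -> 0", {
  pos <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(-4, 0, 0))
  dmg <- make_damage(pos, rep("simple", 4))
  rp <- repair_params(misjoin_sigma = 0, complex_unrepaired_prob = 0)
  for (s in 1:10) {
    out <- repair_run(dmg, rp, rng_seed = s)
    expect_identical(out$n_correct, 4L)
  }
})

test_that("end-state partition is conserved on every run", {
  set.seed(33)
  cl <- build_cluster(cell_geometry(1), "lattice_3d", "Lu177")
  cla <- build_cluster(cell_geometry(1), "lattice_3d", "Ac225")
  for (i in 1:6) {
    dmg <- if (i %% 2 == 0) {
      simulate_lu_run(cl, 1500, "internalized", rng_seed = 100 + i)
    } else {
      simulate_ac_run(cla, plan_sources(cla, "internalized", 4,
                                        rng_seed = 200 + i),
                      rng_seed = 300 + i)
    }
    out <- repair_run(dmg, rng_seed = i)
    expect_identical(out$n_correct + out$n_misrepaired + out$n_residual,
                     out$n_initial)
    expect_identical(out$n_initial, nrow(dmg$dsbs))
    expect_identical(out$n_post, out$n_misrepaired + out$n_residual)
    expect_true(all(c(out$n_correct, out$n_misrepaired, out$n_residual) >= 0))
  }
})

test_that("the kinetic closed-form limit exp(-lambda t) is recovered as sigma -> 0", {
  # 400 isolated breaks on a wide grid, short window: survival is binomial
  # around exp(-lambda * t) per complexity class
  grid <- as.matrix(expand.grid(x = seq(0, 70, by = 10),
                                y = seq(0, 70, by = 10),
                                z = seq(0, 60, by = 10)))[1:400, ]
  rp <- function(t) repair_params(misjoin_sigma = 0,
                                  complex_unrepaired_prob = 0,
                                  repair_time = t)
  out <- repair_run(make_damage(grid, rep("simple", 400)), rp(0.5),
                    rng_seed = 1)
  p_exp <- exp(-2.07 * 0.5)
  expect_lt(abs(out$n_residual / 400 - p_exp),
            3.5 * sqrt(p_exp * (1 - p_exp) / 400))
  out_c <- repair_run(make_damage(grid, rep("complex", 400)), rp(3),
                      rng_seed = 2)
  p_exp_c <- exp(-0.259 * 3)
  expect_lt(abs(out_c$n_residual / 400 - p_exp_c),
            3.5 * sqrt(p_exp_c * (1 - p_exp_c) / 400))
})

test_that("misrepair increases with DSB spatial density", {
  set.seed(55)
  n <- 120
  u <- matrix(rnorm(3 * n), ncol = 3)
  base <- 4.65 * u / sqrt(rowSums(u^2)) * runif(n)^(1 / 3)
  mis_frac <- function(scale) {
    dmg <- make_damage(base * scale, rep("simple", n))
    mean(vapply(1:8, function(s) {
      repair_run(dmg, repair_params(complex_unrepaired_prob = 0),
                 rng_seed = s)$n_misrepaired / n
    }, numeric(1)))
  }
  dense <- mis_frac(0.25)
  sparse <- mis_frac(1)
  expect_gt(dense, sparse)
})

test_that("unrepairable complex breaks stay residual", {
  pos <- matrix(rnorm(3 * 50, sd = 1.5), ncol = 3)
  dmg <- make_damage(pos, rep("complex", 50))
  rp <- repair_params(complex_unrepaired_prob = 1)
  out <- repair_run(dmg, rp, rng_seed = 3)
  expect_identical(out$n_residual, 50L)
  expect_identical(out$n_correct, 0L)
})

test_that("mean_post_repair is deterministic given a seed and reports spread", {
  cl <- build_cluster(cell_geometry(1), "lattice_3d", "Lu177")
  dmg <- simulate_lu_run(cl, 2000, "internalized", rng_seed = 77)
  a <- mean_post_repair(dmg, repair_params(repetitions = 4), rng_seed = 5)
  b <- mean_post_repair(dmg, repair_params(repetitions = 4), rng_seed = 5)
  expect_identical(a, b)
  expect_identical(length(a$n_post), 4L)
  expect_gte(a$sd, 0)
})
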