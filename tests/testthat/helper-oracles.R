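# Independent brute-force oracles used by the unit tests. These deliberately
# avoid the package's own sampling/transport code paths.

# Area-weighted draw from a fine lat-long triangulation of an ellipsoid
# surface: patches are chosen multinomially by numerically integrated area,
# points are jittered uniformly in parameter space within the patch.
oracle_ellipsoid_surface <- function(half_lengths, n, n_theta = 200, n_phi = 400) {
  a <- half_lengths[1]; b <- half_lengths[2]; c <- half_lengths[3]
  dth <- pi / n_theta
  dph <- 2 * pi / n_phi
  th <- (seq_len(n_theta) - 0.5) * dth
  ph <- (seq_len(n_phi) - 0.5) * dph
  grid <- expand.grid(th = th, ph = ph)
  # |r_theta x r_phi| for r = (a sin t cos p, b sin t sin p, c cos t)
  st <- sin(grid$th); ct <- cos(grid$th)
  sp <- sin(grid$ph); cp <- cos(grid$ph)
  ex <- b * c * st^2 * cp
  ey <- a * c * st^2 * sp
  ez <- a * b * st * ct
  area <- sqrt(ex^2 + ey^2 + ez^2) * dth * dph
  pick <- sample.int(nrow(grid), n, replace = TRUE, prob = area)
  tj <- grid$th[pick] + stats::runif(n, -dth / 2, dth / 2)
  pj <- grid$ph[pick] + stats::runif(n, -dph / 2, dph / 2)
  cbind(a * sin(tj) * cos(pj), b * sin(tj) * sin(pj), c * cos(tj))
}

# Ray-march estimate of the chord length of a ray through a sphere at the
# origin: samples the indicator of "inside" on a fine arc-length grid
# restricted to the only window where the sphere can be met.
oracle_ray_march_chord <- function(origin, direction, radius, step = 5e-4) {
  d0 <- sqrt(sum(origin^2))
  s <- seq(max(d0 - radius - 2 * step, 0), d0 + radius + 2 * step, by = step)
  p2 <- outer(s, direction[1], function(si, d) origin[1] + si * d)^2 +
    outer(s, direction[2], function(si, d) origin[2] + si * d)^2 +
    outer(s, direction[3], function(si, d) origin[3] + si * d)^2
  sum(p2 <= radius^2) * step
}

# Build a damage record directly (bypassing the simulators) for repair tests.
make_damage <- function(pos, complexity, dose = 1, nuclide = "Lu177") {
  structure(list(
    dose_Gy = dose,
    dsbs = data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      complexity = complexity),
    nuclide = nuclide, run_seed = NA_integer_),
    class = "damage_record")
}
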