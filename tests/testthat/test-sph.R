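test_that("Lucy kernel has compact support, the right centre value, and unit mass", {
  h <- 4.71e-3
  k <- lucy_kernel(c(0, h / 2, h, 2 * h), h)
  expect_equal(k$w[1], 105 / (16 * pi * h^3))
  expect_equal(k$w[3], 0)
  expect_equal(k$dw[3], 0)
  expect_equal(k$w[4], 0)
  # volume integral of W over its support equals 1 (quadrature)
  q <- integrate(function(r) 4 * pi * r^2 * lucy_kernel(r, h)$w, 0, h,
                 rel.tol = 1e-9)
  expect_lt(abs(q$value - 1), 1e-6)
  # gradient consistent with a numerical derivative
  r0 <- seq(0.1, 0.9, by = 0.2) * h
  eps <- 1e-9
  num <- (lucy_kernel(r0 + eps, h)$w - lucy_kernel(r0 - eps, h)$w) / (2 * eps)
  expect_equal(lucy_kernel(r0, h)$dw, num, tolerance = 1e-4)
})

test_that("Tait pressure matches the closed form and is monotone", {
  expect_equal(tait_pressure(1017, 1017, 0.1), 0)
  expect_equal(tait_pressure(1.01 * 1017, 1017, 0.1),
               0.1^2 * 1017 / 7 * (1.01^7 - 1))
  rho <- seq(900, 1300, by = 10)
  expect_true(all(diff(tait_pressure(rho, 1017, 0.1)) > 0))
})

test_that("contact potential is a finite-energy soft core with interior maximum", {
  A <- 1e-5; rc <- 2.35e-3
  cf <- contact_force(c(0, rc / 2, rc, 2 * rc), A, rc)
  expect_equal(cf$energy[1], 2 * A)
  expect_equal(cf$force[1], 0)
  expect_equal(cf$energy[3], 0, tolerance = 1e-20)
  expect_equal(cf$force[3], 0, tolerance = 1e-20)
  expect_equal(cf$energy[4], 0)
  # maximal repulsion at rc / 2
  r <- seq(0, rc, length.out = 201)
  expect_equal(r[which.max(contact_force(r, A, rc)$force)], rc / 2,
               tolerance = rc / 200)
  expect_equal(max(contact_force(r, A, rc)$force), A * pi / rc)
})

test_that("continuity rate is Galilean invariant and detects compression", {
  dx <- 2.351e-3
  ax <- (0:5) * dx
  g <- expand.grid(x = ax, y = ax, z = ax)
  p <- particle_tbl(g$x, g$y, g$z, vx = 0.37, vy = -0.11, vz = 0.05)
  params <- sph_params(lattice_spacing = dx, gravity = c(0, 0, 0))
  dr <- density_rate(p, params)
  expect_equal(max(abs(dr$drho)), 0)
  # two approaching particles compress
  p2 <- particle_tbl(x = c(0, 2e-3), y = c(0, 0), z = c(0, 0),
                     vx = c(0.01, -0.01))
  dr2 <- density_rate(p2, params)
  expect_true(all(dr2$drho > 0))
})

test_that("momentum equation reduces to gravity for a resting pair at rest density", {
  p <- particle_tbl(x = c(0, 2e-3), y = c(0, 0), z = c(0, 0))
  params <- sph_params(lattice_spacing = 2.351e-3)
  a <- momentum_accel(p, params)
  expect_equal(a$ax, c(0, 0))
  expect_equal(a$az, c(-9.81, -9.81))
  # perpendicular relative motion: viscous term vanishes (v_ij . r_ij = 0),
  # so the acceleration is still gravity only
  p2 <- p; p2$vy <- c(0.05, -0.05)
  a2 <- momentum_accel(p2, params)
  expect_equal(a2$ax, c(0, 0), tolerance = 1e-15)
  expect_equal(a2$az, c(-9.81, -9.81))
})

test_that("pair forces are antisymmetric: isolated pair conserves momentum", {
  set.seed(3)
  for (k in 1:5) {
    p <- particle_tbl(x = c(0, runif(1, 1e-3, 8e-3)), y = c(0, runif(1, -3e-3, 3e-3)),
                      z = c(0, runif(1, -3e-3, 3e-3)),
                      vx = runif(2, -0.05, 0.05), vy = runif(2, -0.05, 0.05),
                      vz = runif(2, -0.05, 0.05),
                      density = 1017 * runif(2, 0.95, 1.1))
    params <- sph_params(lattice_spacing = 2.351e-3, gravity = c(0, 0, 0))
    ev <- evaluate_forces(p, params)
    expect_equal(colSums(ev$force), c(0, 0, 0), tolerance = 1e-18)
  }
})

test_that("drift is exact for force-free uniform motion", {
  p <- particle_tbl(x = c(0, 0.1), y = c(0, 0.1), z = c(0, 0.1),
                    vx = 0.02, vy = -0.01, vz = 0.005)
  params <- sph_params(lattice_spacing = 2.351e-3, gravity = c(0, 0, 0))
  sim <- simulate_particles(p, params, duration = 0.05, dt = 5e-4,
                            snapshot_every = 0, init_hydrostatic = FALSE)
  n <- 0.05 / 5e-4
  expect_equal(sim$particles$x, p$x + n * 5e-4 * 0.02, tolerance = 1e-14)
  expect_equal(sim$particles$y, p$y - n * 5e-4 * 0.01, tolerance = 1e-14)
})

test_that("a single particle under gravity follows the closed-form kinematics", {
  p <- particle_tbl(x = 0, y = 0, z = 0)
  params <- sph_params(lattice_spacing = 2.351e-3)
  sim <- simulate_particles(p, params, duration = 0.5, dt = 5e-4,
                            snapshot_every = 0, init_hydrostatic = FALSE,
                            vmax_abort = 100)
  t <- sim$time
  expect_equal(sim$particles$z, -0.5 * 9.81 * t^2, tolerance = 1e-10)
})

test_that("a resting periodic lattice stays at rest density", {
  dx <- 2.351e-3; n <- 10
  ax <- (seq_len(n) - 0.5) * dx
  g <- expand.grid(x = ax, y = ax, z = ax)
  p <- particle_tbl(g$x, g$y, g$z, mass = 1017 * dx^3)
  per <- list(px = TRUE, py = TRUE, pz = TRUE, lo = c(0, 0, 0), hi = rep(n * dx, 3))
  params <- sph_params(lattice_spacing = dx, gravity = c(0, 0, 0))
  sim <- simulate_particles(p, params, duration = 0.5, dt = 5e-4,
                            snapshot_every = 0, periodic = per,
                            init_hydrostatic = FALSE)
  expect_equal(sim$status, "ok")
  expect_lt(max(abs(sim$particles$density - 1017)) / 1017, 0.01)
  expect_lt(max(abs(sim$particles$vx)), 1e-12)
})

test_that("total momentum of an isolated periodic box is conserved", {
  dx <- 2.351e-3; n <- 8
  ax <- (seq_len(n) - 0.5) * dx
  g <- expand.grid(x = ax, y = ax, z = ax)
  set.seed(5)
  p <- particle_tbl(g$x, g$y, g$z,
                    vx = rnorm(nrow(g), 0, 0.005), vy = rnorm(nrow(g), 0, 0.005),
                    vz = rnorm(nrow(g), 0, 0.005), mass = 1017 * dx^3)
  per <- list(px = TRUE, py = TRUE, pz = TRUE, lo = c(0, 0, 0), hi = rep(n * dx, 3))
  params <- sph_params(lattice_spacing = dx, gravity = c(0, 0, 0))
  mom0 <- colSums(p$mass * cbind(p$vx, p$vy, p$vz))
  nsteps <- 200
  sim <- simulate_particles(p, params, duration = nsteps * 5e-4, dt = 5e-4,
                            snapshot_every = 0, periodic = per,
                            init_hydrostatic = FALSE)
  mom1 <- colSums(sim$particles$mass *
                  cbind(sim$particles$vx, sim$particles$vy, sim$particles$vz))
  expect_lt(max(abs(mom1 - mom0)), 1e-12 * nsteps)
})

test_that("instability aborts with a diagnostic snapshot", {
  p <- particle_tbl(x = c(0, 1e-4), y = c(0, 0), z = c(0, 0),
                    vx = c(2, -2))
  params <- sph_params(lattice_spacing = 2.351e-3, gravity = c(0, 0, 0))
  sim <- simulate_particles(p, params, duration = 0.01, dt = 5e-4,
                            snapshot_every = 0.001, init_hydrostatic = FALSE)
  expect_equal(sim$status, "unstable")
  expect_gt(length(sim$snapshots), 0)
})
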