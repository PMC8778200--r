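test_that("rasterised uniform flow reproduces the per-pixel flow rate", {
  dx <- 1e-3
  ax <- seq(-0.018, 0.018, by = dx)
  g <- expand.grid(x = seq(0, 8e-3, by = dx), y = ax, z = ax)
  keep <- g$y^2 + g$z^2 < 0.018^2
  p <- particle_tbl(g$x[keep], g$y[keep], g$z[keep], vx = 0.01)
  gr <- rasterize_slice(p, x_plane = 4e-3, L = 1.1e-3, slab = 8e-3)
  expect_equal(unique(round(gr$vx[!gr$masked], 12)), 0.01)
  expect_equal(unique(round(gr$q[!gr$masked], 16)), 0.01 * 1.1e-3^2)
  # no particles: fully masked grid
  empty <- rasterize_slice(p[0, ], x_plane = 4e-3)
  expect_true(all(empty$masked))
})

test_that("pixel flow rates integrate to the slab's volumetric flow", {
  dx <- 1.5e-3
  ax <- seq(-0.0185, 0.0185, by = dx)
  g <- expand.grid(x = seq(0, 8e-3, by = dx), y = ax, z = ax)
  keep <- g$y^2 + g$z^2 < 0.017^2
  vx <- 0.01 + 0.3 * g$y[keep] + 0.2 * g$z[keep]
  p <- particle_tbl(g$x[keep], g$y[keep], g$z[keep], vx = vx,
                    mass = 1017 * dx^3)
  # mask circle aligned with the fluid extent so the neighbour fill only
  # closes interior holes
  gr <- rasterize_slice(p, x_plane = 4e-3, L = 1.1e-3, slab = 8.5e-3,
                        lumen_radius = 0.0171)
  q_grid <- sum(gr$q[!gr$masked])
  q_particles <- sum(p$vx * p$mass / p$density) / 8.5e-3
  expect_lt(abs(q_grid - q_particles) / abs(q_particles), 0.05)
})

test_that("pixel shear stencils recover linear fields per dialect", {
  dx <- 1e-3
  ax <- seq(-0.018, 0.018, by = dx)
  g <- expand.grid(x = seq(0, 8e-3, by = dx), y = ax, z = ax)
  keep <- g$y^2 + g$z^2 < 0.018^2
  cgrad <- 2.5
  p <- particle_tbl(g$x[keep], g$y[keep], g$z[keep], vx = cgrad * g$y[keep])
  # pixels aligned with the particle lattice: pixel values exactly linear
  gr <- rasterize_slice(p, x_plane = 4e-3, L = 1e-3, slab = 8e-3)
  std <- pixel_shear_map(gr, "standard")
  # interior pixels: exact gradient under the standard (2L) stencil
  interior <- !std$masked & std$y^2 + std$z^2 < 0.012^2
  expect_equal(unique(round(std$gamma_y[interior], 8)), cgrad)
  expect_equal(unique(round(std$gamma_z[interior], 8)), 0)
  # as-printed dialect divides the 2-pixel difference by L: exactly twice
  printed <- pixel_shear_map(gr, "as_printed")
  expect_equal(printed$gamma_y[interior], 2 * std$gamma_y[interior])
  # uniform field: zero shear
  pu <- p; pu$vx <- 0.02
  gu <- pixel_shear_map(rasterize_slice(pu, 4e-3, L = 1e-3, slab = 8e-3))
  expect_equal(max(abs(gu$gamma_norm[interior])), 0)
})

test_that("Frobenius norm combines shear components", {
  expect_equal(sqrt(3^2 + 4^2), 5)
  fix <- make_linear_shear_field(c_y = 3, c_z = 4)
  sr <- particle_shear_rate(fix$particles, viscosity = 0.026, h = fix$h)
  interior <- fix$interior(fix$particles)
  expect_equal(mean(sr$gamma_dot[interior]), 5, tolerance = 0.05 * 5)
})

test_that("particle shear rates pass rigid-motion and linear-field oracles", {
  fix <- make_linear_shear_field(c_y = 0, c_z = 0)
  fix$particles$vx <- 0.03   # rigid translation
  sr <- particle_shear_rate(fix$particles, viscosity = 0.026, h = fix$h)
  expect_equal(max(sr$gamma_dot), 0)
  # v_x = c z with c = 1: interior gamma within 5%
  fix1 <- make_linear_shear_field(c_y = 0, c_z = 1)
  sr1 <- particle_shear_rate(fix1$particles, viscosity = 0.026, h = fix1$h)
  interior <- fix1$interior(fix1$particles)
  expect_lt(max(abs(sr1$gamma_dot[interior] - 1)), 0.05)
  # stress arithmetic: tau = eta gamma
  expect_equal(sr1$tau_zx, 0.026 * sr1$dvx_dz)
  i <- which(interior)[1]
  expect_equal(sr1$gamma_dot[i], sr1$tau_norm[i] / 0.026)
})

test_that("stress-detour arithmetic matches the printed example", {
  # tau_yx = 0.026 Pa, tau_zx = 0 at eta = 26 mPa s -> gamma = 1 1/s
  expect_equal(sqrt(0.026^2 + 0^2) / 0.026, 1)
})

test_that("cross-section series handles rest, plug flow and empty slabs", {
  spec <- geometry_spec()
  dom <- build_domain(spec, fill_spec(150e-6, "LOVIS", resolution = 3))
  params <- sph_params(resolution = 3, lattice_spacing = 7e-3)
  p <- dom$particles
  # fabricate a one-snapshot "simulation" at rest
  sim <- list(particles0 = p,
              snapshots = list(list(time = 0,
                                    pos = cbind(p$x, p$y, p$z),
                                    vel = cbind(p$vx, p$vy, p$vz),
                                    dens = p$density)),
              params = params)
  cs <- cross_section_series(sim, x_plane = 0.036, spec = spec)
  expect_equal(cs$mean_vx, 0)
  expect_equal(cs$occlusion, 0, tolerance = 1e-9)
  # uniform plug flow: mean = central = top4 = u
  p2 <- p; p2$vx[p2$kind == "fluid"] <- 0.02
  sim2 <- sim
  sim2$snapshots[[1]]$vel <- cbind(p2$vx, p2$vy, p2$vz)
  cs2 <- cross_section_series(sim2, x_plane = 0.036, spec = spec)
  expect_equal(cs2$mean_vx, 0.02)
  expect_equal(cs2$top4_vx, 0.02, tolerance = 1e-12)
  # empty slab (beyond the fluid): missing, not zero
  cs3 <- cross_section_series(sim, x_plane = 0.5, spec = spec)
  expect_true(is.na(cs3$mean_vx))
  expect_equal(cs3$n_particles, 0L)
})

test_that("bottom-wall shear series: rest gives zero, mean <= max", {
  spec <- geometry_spec()
  dom <- build_domain(spec, fill_spec(150e-6, "LOVIS", resolution = 3))
  p <- dom$particles
  sim <- list(particles0 = p,
              snapshots = list(list(time = 0, pos = cbind(p$x, p$y, p$z),
                                    vel = cbind(p$vx, p$vy, p$vz),
                                    dens = p$density)),
              params = sph_params(resolution = 3, lattice_spacing = 7e-3))
  class(sim) <- "dmp_sim"
  sh <- bottom_wall_shear_series(sim, window = c(0.12, 0.144),
                                 viscosity = 0.026, segment = 6)
  expect_equal(sh$mean_shear, 0)
  expect_equal(sh$max_shear, 0)
  expect_true(all(sh$mean_shear <= sh$max_shear))
  expect_gt(sh$n_layer, 0)
})

test_that("TSS matches hand arithmetic, is symmetric, and needs overlap", {
  a <- tibble::tibble(time = c(0, 1), value = c(1, 2))
  b <- tibble::tibble(time = c(0, 1), value = c(0, 0))
  expect_equal(tss(a, a), 0)
  expect_equal(tss(a, b), 5)
  expect_equal(tss(a, b), tss(b, a))
  # resampling onto the coarser grid
  fine <- tibble::tibble(time = seq(0, 1, by = 0.1), value = seq(0, 1, by = 0.1))
  coarse <- tibble::tibble(time = c(0, 0.5, 1), value = c(0, 0, 0))
  expect_equal(tss(fine, coarse), 0^2 + 0.5^2 + 1^2)
  late <- tibble::tibble(time = c(5, 6), value = c(0, 0))
  expect_error(tss(a, late), "disjoint")
})

test_that("main effects recover constructed factorials", {
  grid <- expand.grid(wave_speed = c(0.004, 0.008),
                      viscosity = c("LOVIS", "HIVIS"),
                      volume = c(150, 200), stringsAsFactors = FALSE)
  # all equal responses: zero effects, p = 1
  grid$y <- 5
  me <- main_effects(grid, response = "y",
                     factors = c("wave_speed", "viscosity", "volume"))
  expect_equal(me$effect, c(0, 0, 0))
  # response = viscosity indicator: viscosity effect 1, others 0
  grid$y <- as.numeric(grid$viscosity == "LOVIS")  # low level is HIVIS alphabetically
  me2 <- main_effects(grid, response = "y",
                      factors = c("wave_speed", "viscosity", "volume"))
  expect_equal(me2$effect[me2$factor == "viscosity"], 1)
  expect_equal(me2$effect[me2$factor != "viscosity"], c(0, 0))
  expect_lt(me2$p_value[me2$factor == "viscosity"], 0.05)
  # effect invariant under relabelling of the other two factors
  set.seed(9)
  grid$y <- rnorm(8)
  base <- main_effects(grid, response = "y",
                       factors = c("wave_speed", "viscosity", "volume"))
  swapped <- grid
  swapped$wave_speed <- ifelse(grid$wave_speed == 0.004, "a", "b")
  swapped$volume <- ifelse(grid$volume == 150, "v1", "v2")
  alt <- main_effects(swapped, response = "y",
                      factors = c("wave_speed", "viscosity", "volume"))
  expect_equal(alt$effect[alt$factor == "viscosity"],
               base$effect[base$factor == "viscosity"])
  # incomplete factorial rejected
  expect_error(main_effects(grid[-1, ], response = "y",
                            factors = c("wave_speed", "viscosity", "volume")),
               "incomplete")
})
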