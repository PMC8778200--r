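test_that("Hookean bond and tether forces follow Hooke's law pairwise", {
  # two bonded particles at rest length: zero force
  p <- particle_tbl(x = c(0, 6.283e-3), y = c(0, 0), z = c(0, 0),
                    kind = "membrane_fixed")
  net <- list(bond_i = 1L, bond_j = 2L, bond_l0 = 6.283e-3,
              k_bond = 0.1, k_tether = 0, k_damp = 0,
              anchors = cbind(p$x, p$y, p$z))
  class(net) <- "spring_network"
  expect_equal(hookean_forces(net, p), matrix(0, 2, 3))
  # extension of 1e-3 m at k = 0.1 J m^-2 gives |F| = 1e-4 N, equal/opposite
  p2 <- p; p2$x[2] <- p$x[2] + 1e-3
  f <- hookean_forces(net, p2)
  expect_equal(f[1, 1], 1e-4, tolerance = 1e-12)
  expect_equal(f[1, ], -f[2, ])
  expect_equal(colSums(f), c(0, 0, 0))
  # coincident bonded pair: zero force with a warning
  p3 <- p; p3$x[2] <- p3$x[1]
  expect_warning(f3 <- hookean_forces(net, p3), "coincident")
  expect_equal(f3, matrix(0, 2, 3))
})

test_that("internal bond forces sum to zero over a perturbed membrane", {
  spec <- geometry_spec()
  dom <- build_domain(spec, fill = NULL)
  p <- dom$particles
  set.seed(7)
  memb <- p$kind %in% c("membrane_mobile", "membrane_fixed")
  p$y[memb] <- p$y[memb] + rnorm(sum(memb), 0, 5e-4)
  p$z[memb] <- p$z[memb] + rnorm(sum(memb), 0, 5e-4)
  net_bonds_only <- dom$network
  net_bonds_only$k_tether <- 0
  f <- hookean_forces(net_bonds_only, p)
  expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-15)
  # every mobile membrane particle is tethered
  expect_true(all(rowSums(dom$network$anchors[p$kind == "membrane_mobile", ]^2) >= 0))
})

test_that("spring network bonds follow the lattice proximity rule", {
  dom <- build_domain(geometry_spec(), fill = NULL)
  net <- dom$network
  p <- dom$particles
  l <- sqrt((p$x[net$bond_i] - p$x[net$bond_j])^2 +
            (p$y[net$bond_i] - p$y[net$bond_j])^2 +
            (p$z[net$bond_i] - p$z[net$bond_j])^2)
  expect_equal(l, net$bond_l0)
  # all bonds within the 1.5 x max-spacing cut-off
  expect_lt(max(l), 1.5 * 6.283e-3)
  # symmetric listing: each pair once
  key <- paste(pmin(net$bond_i, net$bond_j), pmax(net$bond_i, net$bond_j))
  expect_equal(anyDuplicated(key), 0)
})

test_that("damping force is linear and dissipative", {
  expect_equal(damping_force(1e-2, c(0.1, 0, 0)), c(-1e-3, 0, 0))
  expect_equal(damping_force(1e-2, c(0, 0, 0)), c(0, 0, 0))
  set.seed(1)
  v <- matrix(rnorm(30), 10, 3)
  f <- damping_force(1e-2, v)
  expect_true(all(rowSums(f * v) <= 0))
})

test_that("motility schedule reproduces the wave arithmetic", {
  slow <- motility_program(wave_speed = 0.004)
  fast <- motility_program(wave_speed = 0.008)
  # segment offsets: (k-1) * segment_length / wave_speed
  expect_equal(slow$offsets, (0:9) * 0.024 / 0.004)
  expect_equal(slow$offsets[10], 54)
  expect_equal(fast$offsets, (0:9) * 3)
  # traversal of the 0.24 m section: 60 s slow, 30 s fast
  expect_equal(wave_traversal_time(slow), 60)
  expect_equal(wave_traversal_time(fast), 30)
  # zero force before a segment's offset; signs per phase
  prog <- slow
  prog$amp_contract <- 1e-3; prog$amp_relax <- 5e-4
  expect_equal(motility_force(prog, 10, 53.9), 0)
  expect_equal(motility_force(prog, 1, 0.5), -5e-4)        # outward relax
  expect_equal(motility_force(prog, 1, 2.5), 1e-3)         # inward contract
  t_ret <- 0.6 * 6 + 0.7 * 6                               # mid slow-return
  expect_equal(motility_force(prog, 1, t_ret), 1e-3 * 0.5)
  expect_equal(motility_force(prog, 1, 100), 0)
  # slow return lasts longer than contraction
  expect_gt(prog$f_return, prog$f_contract)
  expect_error(motility_program(f_return = 0.2), "longer")
})

test_that("membrane relaxes toward tether anchors under damping", {
  spec <- geometry_spec(total_length = 0.13, dcm_length = 0.125,
                        n_segments = 1L)
  dom <- build_domain(spec, fill = NULL)
  p <- dom$particles
  set.seed(11)
  mob <- p$kind == "membrane_mobile"
  p$y[mob] <- p$y[mob] * 0.9
  p$z[mob] <- p$z[mob] * 0.9
  params <- sph_params(lattice_spacing = NULL)
  tether_energy <- function(pp) {
    d2 <- (pp$x - dom$network$anchors[, 1])^2 +
      (pp$y - dom$network$anchors[, 2])^2 +
      (pp$z - dom$network$anchors[, 3])^2
    0.5 * dom$network$k_tether * sum(d2[mob])
  }
  sim <- simulate_particles(p, params, network = dom$network, duration = 1,
                            dt = 2.5e-3, snapshot_every = 0.25)
  e <- vapply(seq_along(sim$snapshots), function(k)
    tether_energy(snapshot_particles(sim, k)), numeric(1))
  expect_lt(e[length(e)], e[1])
  expect_true(all(diff(e) < 0))
})
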