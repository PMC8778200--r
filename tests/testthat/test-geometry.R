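test_that("membrane ring counts reproduce the printed particle totals", {
  m <- build_membrane()
  expect_equal(nrow(m), 2500)                       # one layer over 0.622 m
  dcm <- m[m$kind != "tank_wall", ]
  expect_equal(nrow(dcm), 975)                      # colon section, 39 rings
  expect_equal(length(unique(dcm$ring)), 39)
  expect_equal(max(table(dcm$ring)), 25)
  # 3 fixed rows over 39 rings
  expect_equal(sum(m$kind == "membrane_fixed"), 3 * 39)
  # segment pattern: 10 segments x 3 mobile rings + 9 shared boundary rings
  seg_rings <- table(unique(dcm[!is.na(dcm$segment), c("ring", "segment")])$segment)
  expect_true(all(seg_rings == 3))
  expect_equal(length(unique(dcm$ring[is.na(dcm$segment)])), 9)
  # all membrane particles carry the membrane particle mass
  expect_true(all(dcm$mass == 3.89e-4))
})

test_that("ring counts follow floor(L / r0) + 1 on arbitrary spans", {
  spec <- geometry_spec()
  for (L in c(0.05, 0.1, 0.24, 0.4, 0.622)) {
    m <- build_membrane(geometry_spec(total_length = L, dcm_length = L / 2,
                                      n_segments = 1L))
    expect_equal(length(unique(m$ring)),
                 floor(L / spec$ring_spacing + 0.01) + 1)
  }
})

test_that("a minimal ring spec builds a square cross-section", {
  spec <- geometry_spec(total_length = 6.3e-3, dcm_length = 6.29e-3,
                        particles_per_ring = 4L, n_segments = 1L,
                        ring_spacing = 6.283e-3, n_fixed_rows = 1L)
  # 2 rings x 4 particles
  m <- build_membrane(spec)
  expect_equal(nrow(m), 8)
  r1 <- m[m$ring == 1, ]
  d <- as.matrix(dist(cbind(r1$y, r1$z)))
  side <- sqrt(2) * spec$inner_radius
  expect_equal(sort(unique(round(d[upper.tri(d)], 10))),
               round(c(side, 2 * spec$inner_radius), 10))
})

test_that("specs that cannot host 3 distinct fixed rows are rejected", {
  expect_error(geometry_spec(particles_per_ring = 2L))
})

test_that("fluid fill reproduces the printed particle count and volume", {
  f <- fill_fluid(geometry_spec(), fill_spec(150e-6, "LOVIS"))
  expect_lt(abs(nrow(f) - 11507) / 11507, 0.01)
  expect_lt(abs(sum(f$mass / f$density) - 150e-6) / 150e-6, 0.02)
  # derived lattice spacing matches mass/density arithmetic
  fs <- fill_spec(150e-6, "LOVIS")
  expect_equal(fs$lattice_spacing, (1.324e-5 / 1017)^(1 / 3), tolerance = 1e-6)
})

test_that("fill volume is conserved within 2% over a volume grid", {
  spec <- geometry_spec()
  for (vol in seq(10e-6, 250e-6, by = 40e-6)) {
    f <- fill_fluid(spec, fill_spec(vol, "LOVIS"))
    expect_lt(abs(sum(f$mass / f$density) - vol) / vol, 0.02)
  }
})

test_that("fill is bottom-up, monotone in volume, and capacity-checked", {
  spec <- geometry_spec()
  f60 <- fill_fluid(spec, fill_spec(150e-6, "LOVIS", resolution = 2))
  f80 <- fill_fluid(spec, fill_spec(200e-6, "LOVIS", resolution = 2))
  expect_gt(nrow(f80), nrow(f60))
  expect_gt(min(f80$z) - 1e-12, -spec$inner_radius)
  # gas space remains above the 60% fill surface
  expect_lt(max(f60$z), spec$inner_radius - 4e-3)
  expect_lt(max(f60$z), max(f80$z))
  # single-particle fill sits at the lumen bottom
  fs <- fill_spec(150e-6, "LOVIS")
  f1 <- fill_fluid(spec, fill_spec(fs$particle_mass / fs$density, "LOVIS"))
  expect_equal(nrow(f1), 1)
  expect_lt(f1$z, -spec$inner_radius / 2)
  expect_error(fill_fluid(spec, fill_spec(400e-6, "LOVIS")), "capacity")
})

test_that("occlusion degree follows its definition and is rotation invariant", {
  th <- 2 * pi * (0:21) / 22
  ring <- particle_tbl(x = 0 * th, y = 0.008 * cos(th), z = 0.008 * sin(th),
                       kind = "membrane_mobile")
  expect_equal(occlusion_degree(ring, 0.02), 60)
  ring$y <- 0.024 * cos(th); ring$z <- 0.024 * sin(th)
  expect_equal(occlusion_degree(ring, 0.02), -20)
  ring$y <- 0.02 * cos(th); ring$z <- 0.02 * sin(th)
  expect_equal(occlusion_degree(ring, 0.02), 0)
  # rigid rotation about the tube axis
  set.seed(42)
  r <- 0.02 * runif(22, 0.4, 1.2)
  base <- particle_tbl(x = 0 * th, y = r * cos(th), z = r * sin(th),
                       kind = "membrane_mobile")
  for (rot in c(0.3, 1.2, 2.5)) {
    rotated <- base
    rotated$y <- r * cos(th + rot); rotated$z <- r * sin(th + rot)
    expect_equal(occlusion_degree(rotated, 0.02),
                 occlusion_degree(base, 0.02), tolerance = 1e-12)
  }
})

test_that("build_domain assembles membrane, constriction and fluid", {
  d <- build_domain(geometry_spec(), fill_spec(150e-6, "LOVIS", resolution = 3))
  p <- d$particles
  # counted (inner) shell: 2500 particles over the full tube
  expect_equal(sum(!is.na(p$ring) & p$layer == 1), 2500)
  expect_gt(sum(p$kind == "fluid"), 0)
  # staggered outer cage present
  expect_gt(sum(!is.na(p$ring) & p$layer == 2), 0)
  expect_true(all(d$particles$density > 0))
  # constriction sits at the colon/tank junction with reduced radius
  con <- d$particles[d$particles$kind == "tank_wall" &
                     d$particles$x >= 0.24 - 1e-9 &
                     d$particles$x <= 0.24 + 2 * 6.283e-3, ]
  expect_true(any(abs(sqrt(con$y^2 + con$z^2) - 0.4 * 0.02) < 1e-9))
  # dry domain
  dry <- build_domain(geometry_spec(), fill = NULL)
  expect_equal(sum(dry$particles$kind == "fluid"), 0)
})

test_that("overlapping particles are rejected", {
  d <- build_domain(geometry_spec(), fill_spec(150e-6, "LOVIS", resolution = 3))
  p <- d$particles
  p[nrow(p) + 1, ] <- p[nrow(p), ]   # duplicate a particle
  expect_error(dcmtwin:::check_overlaps(p, 7e-3), "overlap")
})
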