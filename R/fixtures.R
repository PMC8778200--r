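#' Hydrostatic-column validation fixture
#'
#' A still fluid column over a three-layer bottom wall plate in a laterally
#' periodic box. After settling, the Tait pressure profile should follow
#' the hydrostatic reference `P(z) = rho0 g (z_surf - z)`.
#'
#' The fixture uses its own artificial sound speed (default 2.5 m s^-1): the
#' incompressible reference requires the weakly compressible regime
#' `c0^2 >> g * depth`, under which density varies only a few percent over
#' the column.
#'
#' @param depth Column depth (m).
#' @param preset Fluid preset name.
#' @param dx Lattice spacing (m).
#' @param width Box width in lattice cells (kept >= 13 so the periodic cell
#'   list stays valid).
#' @param c0 Artificial sound speed for the fixture (m s^-1).
#' @return A `fixture_case` list: `particles`, `params`, `periodic`,
#'   `reference` (function of z, Pa), `tolerance`, and suggested `settle`
#'   and `duration` times.
#' @export
make_hydrostatic_case <- function(depth = 0.03, preset = "LOVIS",
                                  dx = 2.351e-3, width = 13L, c0 = 2.5) {
  fp <- fluid_preset(preset)
  rho0 <- fp$density
  mass <- rho0 * dx^3
  nz <- round(depth / dx)
  stopifnot(nz >= 3)
  xy <- (seq_len(width) - 0.5) * dx
  zf <- (seq_len(nz) - 0.5) * dx
  zw <- -(seq_len(3) - 0.5) * dx
  lat <- function(zlevels, kind) {
    g <- expand.grid(x = xy, y = xy, z = zlevels)
    tibble(id = NA_integer_, kind = kind, ring = NA_integer_,
           segment = NA_integer_, x = g$x, y = g$y, z = g$z,
           vx = 0, vy = 0, vz = 0, mass = mass, density = rho0)
  }
  particles <- bind_rows(lat(zf, "fluid"), lat(zw, "tank_wall"))
  particles$id <- seq_len(nrow(particles))
  # fixture kernel ratio h_m = 2.6 dx keeps the nearest shell beyond the Lucy
  # kernel inflection (no Swegle compression mode); strong alpha damps the
  # settling transient (irrelevant for a static column)
  params <- sph_params(resolution = 1, viscosity = fp$viscosity, rho0 = rho0,
                       c0 = c0, dt = min(5e-4, 0.2 * 4.71e-3 / c0),
                       h = 2 * dx, h_m = 2.6 * dx, alpha = 0.5,
                       lattice_spacing = dx, contact_rc = dx)
  zs <- depth
  structure(
    list(name = "hydrostatic_column",
         particles = particles, params = params,
         periodic = list(px = TRUE, py = TRUE, pz = FALSE,
                         lo = c(0, 0, -1), hi = c(width * dx, width * dx, 1)),
         reference = function(z) rho0 * 9.81 * pmax(0, zs - z),
         depth = depth, dx = dx, tolerance = 0.10,
         settle = 2.5, settle_damp = 0.998, duration = 1e-4),
    class = "fixture_case")
}

#' Plane Poiseuille validation fixture
#'
#' A periodic channel between two static wall plates, driven by a streamwise
#' body force. The steady analytic profile is
#' `v_x(y) = g_x / (2 nu) * y * (gap - y)` with no-slip planes at `y = 0`
#' and `y = gap`; the centreline velocity is `g_x gap^2 / (8 nu)`. This
#' exercises the unconditional Monaghan viscous term end to end against the
#' target viscosity.
#'
#' @param gap_cells Channel width in lattice cells (the wall-resolution
#'   ratio).
#' @param dx Lattice spacing (m).
#' @param viscosity Dynamic viscosity (Pa s).
#' @param rho0 Rest density (kg m^-3).
#' @param u_max Target centreline velocity (m s^-1); sets the body force and
#'   keeps the flow laminar (Re well below 10 at the defaults).
#' @return A `fixture_case` list with the analytic `reference` (function of
#'   y, m s^-1) and `body_force`.
#' @export
make_poiseuille_case <- function(gap_cells = 17L, dx = 1e-3,
                                 viscosity = 0.026, rho0 = 1017,
                                 u_max = 0.005) {
  gap <- gap_cells * dx
  nu <- viscosity / rho0
  gx <- 8 * nu * u_max / gap^2
  stopifnot(u_max * gap / nu < 10)  # laminar regime
  nxz <- 12L
  xz <- (seq_len(nxz) - 0.5) * dx
  # staggered walls: with the symmetric-mirror no-slip coupling the zero
  # plane sits midway between the first wall and fluid layers, i.e. exactly
  # at y = 0 and y = gap; 4 wall layers cover the momentum kernel support
  yf <- (seq_len(gap_cells) - 0.5) * dx
  yw <- c(-(seq_len(4) - 0.5) * dx, gap + (seq_len(4) - 0.5) * dx)
  mass <- rho0 * dx^3
  lat <- function(ylevels, kind) {
    g <- expand.grid(x = xz, y = ylevels, z = xz)
    tibble(id = NA_integer_, kind = kind, ring = NA_integer_,
           segment = NA_integer_, x = g$x, y = g$y, z = g$z,
           vx = 0, vy = 0, vz = 0, mass = mass, density = rho0)
  }
  particles <- bind_rows(lat(yf, "fluid"), lat(yw, "tank_wall"))
  particles$id <- seq_len(nrow(particles))
  params <- sph_params(resolution = 1, viscosity = viscosity, rho0 = rho0,
                       h = 2 * dx, dt = 2e-3,
                       gravity = c(gx, 0, 0),
                       lattice_spacing = dx,
                       contact_a = 1e-9, contact_rc = dx)
  structure(
    list(name = "plane_poiseuille",
         particles = particles, params = params,
         periodic = list(px = TRUE, py = FALSE, pz = TRUE,
                         lo = c(0, -1, 0), hi = c(nxz * dx, 1, nxz * dx)),
         reference = function(y) gx / (2 * nu) * y * (gap - y),
         gap = gap, dx = dx, body_force = gx, viscosity = viscosity,
         tolerance = 0.05, settle = 0, duration = 6),
    class = "fixture_case")
}

#' Linear shear-field synthetic snapshot
#'
#' Fluid particles on a cubic lattice carrying `v_x = c_y * y + c_z * z`,
#' whose exact shear-rate magnitude is `sqrt(c_y^2 + c_z^2)` everywhere.
#' Validates the particle (SPH-gradient) and pixel (finite-difference)
#' shear estimators.
#'
#' @param c_y,c_z Imposed velocity gradients (s^-1).
#' @param dx Lattice spacing (m).
#' @param n_cells Lattice extent per dimension.
#' @param rho0 Density assigned to the lattice (kg m^-3).
#' @return A `fixture_case` list with `particles`, the exact
#'   `reference_gamma`, and an `interior` predicate (particles at least one
#'   smoothing length from the lattice boundary).
#' @export
make_linear_shear_field <- function(c_y = 1, c_z = 0, dx = 2.351e-3,
                                    n_cells = 12L, rho0 = 1017) {
  ax <- (seq_len(n_cells) - 0.5) * dx
  g <- expand.grid(x = ax, y = ax, z = ax)
  particles <- tibble(
    id = seq_len(nrow(g)), kind = "fluid", ring = NA_integer_,
    segment = NA_integer_, x = g$x, y = g$y, z = g$z,
    vx = c_y * g$y + c_z * g$z, vy = 0, vz = 0,
    mass = rho0 * dx^3, density = rho0)
  h <- 2 * dx
  lo <- h; hi <- n_cells * dx - h
  structure(
    list(name = "linear_shear_field",
         particles = particles, dx = dx, h = h,
         c_y = c_y, c_z = c_z,
         reference_gamma = sqrt(c_y^2 + c_z^2),
         interior = function(p) {
           p$x > lo & p$x < hi & p$y > lo & p$y < hi & p$z > lo & p$z < hi
         },
         tolerance = 0.05),
    class = "fixture_case")
}

#' Run a validation fixture and report pass/fail
#'
#' Executes the fixture's simulation (where it has one) and compares the
#' measured quantity against its analytic reference at the fixture's
#' tolerance.
#'
#' @param case A `fixture_case`.
#' @return Tibble `fixture`, `measured`, `reference`, `rel_error`, `pass`.
#' @export
run_fixture <- function(case) {
  if (case$name == "linear_shear_field") {
    sr <- particle_shear_rate(case$particles, viscosity = 0.026, h = case$h)
    p <- case$particles
    interior <- case$interior(p)
    measured <- mean(sr$gamma_dot[interior])
    ref <- case$reference_gamma
  } else if (case$name == "plane_poiseuille") {
    sim <- simulate_particles(case$particles, case$params,
                              duration = case$duration, dt = case$params$dt,
                              snapshot_every = 0, settle_time = case$settle,
                              periodic = case$periodic,
                              init_hydrostatic = FALSE)
    p <- sim$particles
    centre <- p$kind == "fluid" & abs(p$y - case$gap / 2) <= case$dx
    measured <- mean(p$vx[centre])
    ref <- mean(case$reference(p$y[centre]))
  } else if (case$name == "hydrostatic_column") {
    sim <- simulate_particles(case$particles, case$params,
                              duration = case$duration, dt = case$params$dt,
                              snapshot_every = 0, settle_time = case$settle,
                              settle_damp = case$settle_damp,
                              periodic = case$periodic,
                              init_hydrostatic = FALSE)
    lay <- hydrostatic_profile(sim, case)
    measured <- max(abs(lay$P - lay$ref) / max(lay$ref))
    out <- tibble(fixture = case$name, measured = measured, reference = 0,
                  rel_error = measured, pass = measured < case$tolerance)
    return(out)
  } else {
    abort("unknown fixture")
  }
  rel <- abs(measured - ref) / abs(ref)
  tibble(fixture = case$name, measured = measured, reference = ref,
         rel_error = rel, pass = rel < case$tolerance)
}

# layer-mean kernel-smoothed Tait pressure of a settled column against the
# hydrostatic law rho0 g (depth below the settled free surface). The SPH
# dynamics responds to the kernel-interpolated field, so that is what is
# compared; the surface layer and the contact-supported bottom boundary
# layer are excluded (kernel truncation and wall standoff live there).
hydrostatic_profile <- function(sim, case) {
  p <- sim$particles
  fl <- p$kind == "fluid"
  P_raw <- tait_pressure(pmax(p$density, 1), case$params$rho0, case$params$c0)
  P_raw[!fl] <- 0
  st <- particles_to_cpp(p)
  P_s <- cpp_shepard(st$pos[fl, , drop = FALSE], P_raw[fl],
                     st$mass[fl], st$dens[fl], case$params$h_m)
  zs <- max(p$z[fl]) + 0.5 * case$dx
  zl <- round(p$z[fl] / case$dx - 0.5)
  lay <- tibble(z = (zl + 0.5) * case$dx, zp = p$z[fl], P = P_s) |>
    group_by(.data$z) |>
    summarise(P = mean(.data$P), zbar = mean(.data$zp), .groups = "drop")
  lay <- lay[lay$z > min(lay$z) & lay$z < max(lay$z) - 0.5 * case$dx, ]
  lay$ref <- case$params$rho0 * 9.81 * (zs - lay$zbar)
  lay
}
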