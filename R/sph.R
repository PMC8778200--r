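#' SPH solver parameters
#'
#' Weakly compressible SPH constants. The two-length scheme uses `h` for the
#' continuity (density) equation and `h_m = 2 h` for the momentum equation;
#' the Monaghan-type viscous term is applied to all pairs so that it acts as
#' a real (Newtonian) viscosity with `nu = alpha * h_m * c0 / 10`.
#'
#' At `resolution = 1` the defaults are the full-resolution values
#' (`h = 4.71e-3` m, `dt = 5e-4` s); larger factors scale `h`, `h_m` and
#' `dt` proportionally so the physical viscosity is preserved when `alpha`
#' is recomputed via [alpha_from_viscosity()].
#'
#' @param resolution Scale factor for `h`, `h_m` and `dt`.
#' @param viscosity Target dynamic viscosity (Pa s) used to set `alpha`.
#' @param rho0 Rest density (kg m^-3).
#' @param c0 Artificial speed of sound (m s^-1).
#' @param b Viscous-term regularisation constant.
#' @param h,h_m,dt Override the scaled defaults (m, m, s).
#' @param alpha Override the viscosity-derived value.
#' @param gravity Body-force vector (m s^-2).
#' @param lattice_spacing Fluid lattice spacing (m); sets the contact
#'   cut-off. `NULL` for dry (membrane-only) runs.
#' @param contact_a,contact_rc Contact energy constant (J) and cut-off (m).
#'   The contact is the wall's support: the default cut-off covers the
#'   membrane lattice gaps, and the default strength caps the repulsion at
#'   1.5 x the weight of a lumen-diameter fluid column over one particle
#'   cross-section (see the package vignette).
#' @param wall_visc_scale Factor on the viscous term of fluid-wall pairs; 2
#'   is the symmetric-mirror (Morris-style) no-slip value, 1 the plain
#'   static-wall coupling.
#' @param lumen_radius Used by the default contact-strength rule.
#' @return An `sph_params` list.
#' @export
sph_params <- function(resolution = 1, viscosity = 0.026, rho0 = 1017,
                       c0 = 0.1, b = 0.01,
                       h = 4.71e-3 * resolution, h_m = 2 * h,
                       dt = 5e-4 * resolution,
                       alpha = NULL,
                       gravity = c(0, 0, -9.81),
                       lattice_spacing = 2.351e-3 * resolution,
                       contact_a = NULL, contact_rc = NULL,
                       wall_visc_scale = 2,
                       lumen_radius = 0.02) {
  alpha <- alpha %||% alpha_from_viscosity(viscosity, rho0, h_m, c0)
  if (is.null(lattice_spacing)) {
    contact_a <- contact_a %||% 0
    contact_rc <- contact_rc %||% h
  } else {
    contact_rc <- contact_rc %||% (1.2 * max(lattice_spacing, 5e-3))
    g <- sqrt(sum(gravity^2))
    # peak repulsion scaled to the governing load: hydrostatic column weight
    # under gravity, or a dynamic-pressure floor for wall-driven flow
    contact_a <- contact_a %||%
      (rho0 * lattice_spacing^2 * max(3 * g * 2 * lumen_radius, 0.2) *
         contact_rc / pi)
  }
  if (dt > 0.25 * h / c0)
    warn(sprintf("dt = %.3g exceeds the CFL-type bound 0.25 h / c0 = %.3g",
                 dt, 0.25 * h / c0))
  structure(
    list(h = h, h_m = h_m, c0 = c0, b = b, alpha = alpha, rho0 = rho0,
         gravity = gravity, contact_a = contact_a, contact_rc = contact_rc,
         wall_visc_scale = wall_visc_scale,
         dt = dt, resolution = resolution, viscosity = viscosity,
         lattice_spacing = lattice_spacing),
    class = "sph_params")
}

#' Lucy smoothing kernel (3-D)
#'
#' `W(r, h) = 105 / (16 pi h^3) (1 + 3 r/h)(1 - r/h)^3` for `r < h`, zero
#' outside; normalised so its volume integral is 1.
#'
#' @param r Distance(s), m.
#' @param h Smoothing length, m.
#' @return Tibble with `w` (m^-3) and `dw` (= dW/dr, m^-4).
#' @export
lucy_kernel <- function(r, h) {
  stopifnot(all(r >= 0), h > 0)
  out <- cpp_lucy(as.numeric(r), h)
  tibble(r = as.numeric(r), w = out$w, dw = out$dw)
}

#' Tait equation of state
#'
#' `P = c0^2 rho0 / 7 [(rho/rho0)^7 - 1]` (Pa); stiff barotropic closure of
#' weakly compressible SPH.
#'
#' @param rho Density (kg m^-3), vectorised.
#' @param rho0 Rest density (kg m^-3).
#' @param c0 Artificial speed of sound (m s^-1).
#' @return Pressure(s), Pa.
#' @export
tait_pressure <- function(rho, rho0 = 1017, c0 = 0.1) {
  stopifnot(all(rho > 0))
  cpp_tait(as.numeric(rho), rho0, c0)
}

#' Soft contact repulsion between solid and fluid particles
#'
#' Pair energy `E = A (1 + cos(pi r / rc))` for `r < rc`, giving a purely
#' repulsive force `F = A pi / rc sin(pi r / rc)` with a finite-energy soft
#' core (`E -> 2A`, `F -> 0` as `r -> 0`).
#'
#' @param r Pair distance(s), m.
#' @param contact_a Energy constant A (J).
#' @param contact_rc Cut-off distance (m).
#' @return Tibble with `energy` (J) and `force` (N, repulsive magnitude).
#' @export
contact_force <- function(r, contact_a, contact_rc) {
  stopifnot(all(r >= 0), contact_a >= 0, contact_rc > 0)
  inside <- r < contact_rc
  e <- ifelse(inside, contact_a * (1 + cos(pi * r / contact_rc)), 0)
  f <- ifelse(inside, contact_a * pi / contact_rc * sin(pi * r / contact_rc), 0)
  tibble(r = r, energy = e, force = f)
}

kind_codes <- c(fluid = 0L, membrane_mobile = 1L, membrane_fixed = 2L,
                tank_wall = 3L)

particles_to_cpp <- function(particles) {
  list(pos = cbind(particles$x, particles$y, particles$z),
       vel = cbind(particles$vx, particles$vy, particles$vz),
       mass = particles$mass,
       dens = particles$density,
       kind = unname(kind_codes[particles$kind]),
       seg = ifelse(is.na(particles$segment), 0L, as.integer(particles$segment)))
}

empty_springs <- function(particles) {
  list(bond_i = integer(0), bond_j = integer(0), bond_l0 = numeric(0),
       k_bond = 0, k_tether = 0, k_damp = 0,
       anchors = cbind(particles$x, particles$y, particles$z))
}

springs_to_cpp <- function(network, particles) {
  if (is.null(network)) return(empty_springs(particles))
  list(bond_i = network$bond_i, bond_j = network$bond_j,
       bond_l0 = network$bond_l0,
       k_bond = network$k_bond, k_tether = network$k_tether,
       k_damp = network$k_damp, anchors = network$anchors)
}

periodic_to_cpp <- function(periodic) {
  if (is.null(periodic))
    return(list(px = FALSE, py = FALSE, pz = FALSE,
                lo = c(0, 0, 0), hi = c(1, 1, 1)))
  list(px = isTRUE(periodic$px), py = isTRUE(periodic$py),
       pz = isTRUE(periodic$pz),
       lo = periodic$lo, hi = periodic$hi)
}

sph_to_cpp <- function(params) {
  list(h = params$h, h_m = params$h_m, c0 = params$c0, b = params$b,
       alpha = params$alpha, rho0 = params$rho0, gravity = params$gravity,
       contact_a = params$contact_a, contact_rc = params$contact_rc,
       wall_visc_scale = params$wall_visc_scale %||% 2)
}

#' Evaluate all forces and density rates at the current state
#'
#' One force evaluation of the coupled system: SPH pressure + viscous +
#' gravity on fluid, contact and no-slip coupling across the fluid-wall
#' interface, and spring/tether/damping/motility forces on the membrane.
#'
#' @param particles Particle tibble.
#' @param params An [sph_params()].
#' @param network Optional [spring_network()].
#' @param program Optional [motility_program()] (amplitudes set).
#' @param t Simulation time (s) for the motility schedule.
#' @param periodic Optional periodic box (`list(px, py, pz, lo, hi)`).
#' @return List with `force` (n x 3 matrix, N), `drho` (kg m^-3 s^-1) and
#'   `min_fluid_wall` (m).
#' @export
evaluate_forces <- function(particles, params, network = NULL, program = NULL,
                            t = 0, periodic = NULL) {
  st <- particles_to_cpp(particles)
  cpp_forces(st$pos, st$vel, st$mass, st$dens, st$kind, st$seg,
             sph_to_cpp(params), springs_to_cpp(network, particles),
             motility_cpp(program), periodic_to_cpp(periodic), t)
}

#' Density rate of change from the continuity equation
#'
#' @inheritParams evaluate_forces
#' @return Tibble `id`, `drho` (kg m^-3 s^-1) for fluid particles.
#' @export
density_rate <- function(particles, params, periodic = NULL) {
  ev <- evaluate_forces(particles, params, periodic = periodic)
  if (any(!is.finite(ev$drho[particles$kind == "fluid"])))
    abort("non-finite density rate")
  tibble(id = particles$id, drho = ev$drho)[particles$kind == "fluid", ]
}

#' Particle accelerations from the momentum equation
#'
#' Symmetric pressure term, unconditional Monaghan viscous term (evaluated
#' with the momentum smoothing length `h_m`), gravity, wall contact and
#' no-slip coupling.
#'
#' @inheritParams evaluate_forces
#' @return Tibble `id`, `ax`, `ay`, `az` (m s^-2).
#' @export
momentum_accel <- function(particles, params, network = NULL, program = NULL,
                           t = 0, periodic = NULL) {
  ev <- evaluate_forces(particles, params, network, program, t, periodic)
  tibble(id = particles$id,
         ax = ev$force[, 1] / particles$mass,
         ay = ev$force[, 2] / particles$mass,
         az = ev$force[, 3] / particles$mass)
}

#' Advance the coupled system in time
#'
#' Velocity-Verlet integration of mobile particles (fluid and mobile
#' membrane); fixed-row and tank particles are immobile. Density evolves by
#' the continuity equation. An optional settling phase (time < 0) damps
#' fluid velocities so a freshly placed lattice relaxes against gravity and
#' the walls before the motility clock starts; snapshots are recorded from
#' t = 0 at the requested cadence.
#'
#' @param particles Particle tibble (the initial state).
#' @param params An [sph_params()].
#' @param network Optional [spring_network()].
#' @param program Optional [motility_program()] with amplitudes set.
#' @param duration Simulated time after t = 0 (s).
#' @param dt Time step (s); defaults to `params$dt`.
#' @param snapshot_every Snapshot cadence (s); 0 disables snapshots.
#' @param settle_time Length of the damped settling phase before t = 0 (s).
#' @param settle_damp Per-step velocity damping factor during settling.
#' @param periodic Optional periodic box.
#' @param only_segment Restrict motility to one segment (calibration runs).
#' @param vmax_abort Instability threshold on particle speed (m s^-1);
#'   exceeding it aborts with a diagnostic snapshot.
#' @param init_hydrostatic Initialise fluid density to the hydrostatic
#'   profile implied by gravity and the free surface.
#' @return A `dmp_sim` list: `status`, `time`, `particles` (final state),
#'   `particles0` (initial), `snapshots` (list of `time`, `pos`, `vel`,
#'   `dens`), `diagnostics` tibble.
#' @export
simulate_particles <- function(particles, params, network = NULL,
                               program = NULL, duration, dt = params$dt,
                               snapshot_every = 0.25,
                               settle_time = 0, settle_damp = 0.98,
                               periodic = NULL, only_segment = -1L,
                               vmax_abort = 10 * params$c0,
                               init_hydrostatic = settle_time > 0) {
  if (init_hydrostatic && any(particles$kind == "fluid")) {
    particles <- init_density_hydrostatic(particles, params)
  }
  st <- particles_to_cpp(particles)
  t0 <- -settle_time
  nsteps <- ceiling((duration + settle_time) / dt)
  snap_steps <- if (snapshot_every > 0) max(1L, round(snapshot_every / dt)) else 0L
  res <- cpp_run(st$pos, st$vel, st$mass, st$dens, st$kind, st$seg,
                 sph_to_cpp(params), springs_to_cpp(network, particles),
                 motility_cpp(program, only_segment),
                 periodic_to_cpp(periodic),
                 t0, dt, as.integer(nsteps), as.integer(snap_steps),
                 0.0, settle_damp, vmax_abort)
  final <- particles
  final$x <- res$pos[, 1]; final$y <- res$pos[, 2]; final$z <- res$pos[, 3]
  final$vx <- res$vel[, 1]; final$vy <- res$vel[, 2]; final$vz <- res$vel[, 3]
  final$density <- res$dens
  structure(
    list(status = res$status, time = res$time,
         particles = final, particles0 = particles,
         snapshots = res$snapshots,
         diagnostics = as_tibble(res$diagnostics),
         params = params),
    class = "dmp_sim")
}

# hydrostatic density initialisation: P(z) = rho0 g (z_surf - z) inverted
# through the Tait equation; wall particles below the surface are seeded the
# same way so their pressure supports the column from the first step
init_density_hydrostatic <- function(particles, params) {
  fl <- particles$kind == "fluid"
  if (!any(fl)) return(particles)
  g <- -params$gravity[3]
  if (g <= 0) return(particles)
  zs <- max(particles$z[fl]) + 0.5 * (params$lattice_spacing %||% 0)
  P <- params$rho0 * g * pmax(0, zs - particles$z)
  particles$density <-
    params$rho0 * (1 + 7 * P / (params$rho0 * params$c0^2))^(1 / 7)
  particles
}

#' Extract one snapshot as a particle tibble
#'
#' @param sim A `dmp_sim` from [simulate_particles()].
#' @param index Snapshot index (or `"last"`).
#' @return Particle tibble with the snapshot's positions, velocities and
#'   densities; attribute `time` carries the snapshot time.
#' @export
snapshot_particles <- function(sim, index = "last") {
  if (identical(index, "last")) index <- length(sim$snapshots)
  sn <- sim$snapshots[[index]]
  p <- sim$particles0
  p$x <- sn$pos[, 1]; p$y <- sn$pos[, 2]; p$z <- sn$pos[, 3]
  p$vx <- sn$vel[, 1]; p$vy <- sn$vel[, 2]; p$vz <- sn$vel[, 3]
  p$density <- sn$dens
  attr(p, "time") <- sn$time
  p
}

#' @export
print.dmp_sim <- function(x, ...) {
  cat(sprintf("<dmp_sim> status: %s, t = %.3f s, %d particles, %d snapshots\n",
              x$status, x$time, nrow(x$particles), length(x$snapshots)))
  invisible(x)
}
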