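#' Geometry specification for the colon-mimic tube
#'
#' Describes the particle geometry of the digital twin: a horizontal tube of
#' total length 0.622 m (streamwise `x`, gravity along `-z`) whose first
#' 0.24 m is the dynamic colon section — 10 equal segments of membrane rings,
#' each ring carrying 25 particles — with the remainder acting as a rigid
#' drain tank, separated by an end constriction.
#'
#' Ring counts follow `floor(L / ring_spacing) + 1` with a 1%-of-a-spacing
#' tolerance, so the printed equilibrium spacing of 6.283e-3 m yields 100
#' rings (2500 particles) over the full tube and 39 rings (975 particles)
#' over the colon section.
#'
#' @param total_length Tube length (m).
#' @param dcm_length Length of the dynamic colon section (m).
#' @param inner_radius Lumen radius (m).
#' @param particles_per_ring Particles on each circular ring.
#' @param ring_spacing Axial equilibrium spacing between rings (m).
#' @param n_segments Number of independently actuated segments.
#' @param n_fixed_rows Longitudinal rows of fixed particles shaping the
#'   tri-chamber (haustral) cross-section.
#' @param constriction_radius_fraction End-constriction radius as a fraction
#'   of the lumen radius.
#' @param membrane_particle_mass Mass of one membrane particle (kg).
#' @return A `geometry_spec` list.
#' @export
geometry_spec <- function(total_length = 0.622,
                          dcm_length = 0.24,
                          inner_radius = 0.02,
                          particles_per_ring = 25L,
                          ring_spacing = 6.283e-3,
                          n_segments = 10L,
                          n_fixed_rows = 3L,
                          constriction_radius_fraction = 0.4,
                          membrane_particle_mass = 3.89e-4) {
  if (dcm_length >= total_length) abort("`dcm_length` must be < `total_length`")
  if (particles_per_ring < 3) abort("`particles_per_ring` must be >= 3")
  if (ring_spacing <= 0) abort("`ring_spacing` must be > 0")
  if (particles_per_ring < n_fixed_rows)
    abort("rings cannot host the requested number of distinct fixed rows")
  structure(
    list(total_length = total_length, dcm_length = dcm_length,
         inner_radius = inner_radius,
         particles_per_ring = as.integer(particles_per_ring),
         ring_spacing = ring_spacing, n_segments = as.integer(n_segments),
         n_fixed_rows = as.integer(n_fixed_rows),
         constriction_radius_fraction = constriction_radius_fraction,
         membrane_particle_mass = membrane_particle_mass),
    class = "geometry_spec")
}

# ring count over axial span L: floor(L/r0)+1, tolerant of the printed
# (rounded) spacing under-covering the span by <1% of a spacing
n_rings_over <- function(L, r0) as.integer(floor(L / r0 + 0.01) + 1)

#' Fluid fill specification
#'
#' @param volume Fill volume (m^3); 150e-6 and 200e-6 are the nominal 60% and
#'   80% filling levels.
#' @param preset Fluid preset, `"LOVIS"` (low viscosity) or `"HIVIS"`.
#' @param particle_mass,density Override the preset fluid particle mass (kg)
#'   and rest density (kg m^-3).
#' @param resolution Lattice scale factor; 1 places particles at the native
#'   spacing `(mass/density)^(1/3)` (~2.35 mm), larger values coarsen the
#'   lattice (mass rescaled to keep density).
#' @return A `fill_spec` list with the derived lattice spacing.
#' @export
fill_spec <- function(volume = 150e-6, preset = c("LOVIS", "HIVIS"),
                      particle_mass = NULL, density = NULL, resolution = 1) {
  preset <- match.arg(preset)
  fp <- fluid_preset(preset)
  density <- density %||% fp$density
  m0 <- particle_mass %||% fp$particle_mass
  dx <- (m0 / density)^(1 / 3) * resolution
  mass <- density * dx^3
  if (volume <= 0) abort("`volume` must be > 0")
  structure(
    list(volume = volume,
         fill_fraction_label = if (volume <= 175e-6) 60 else 80,
         preset = preset, particle_mass = mass, density = density,
         lattice_spacing = dx, resolution = resolution),
    class = "fill_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the membrane and tank-wall particle shell
#'
#' Places rings of equally spaced particles along the tube. Rings within the
#' colon section are membrane particles grouped into segments (3 mobile rings
#' per segment, one shared boundary ring between adjacent segments, boundary
#' rings belonging to neither); the particle nearest each of the fixed-row
#' azimuths (90, 210, 330 degrees) in every colon ring is flagged fixed.
#' Remaining rings out to the total length are static tank wall.
#'
#' @param spec A [geometry_spec()].
#' @param layers 1 builds the counted (inner) particle layer; 2 adds a
#'   staggered outer layer (offset half an axial spacing, half an azimuthal
#'   step, and half an azimuthal gap radially outward) that closes the
#'   lattice gap channels of the shell, brick-wall fashion. The printed
#'   particle counts refer to one layer.
#' @return A tibble of particles with columns `id`, `kind`, `layer`, `ring`,
#'   `segment`, `x`, `y`, `z`, `vx`, `vy`, `vz`, `mass`, `density`.
#' @export
build_membrane <- function(spec = geometry_spec(), layers = 1L) {
  stopifnot(inherits(spec, "geometry_spec"), layers %in% c(1L, 2L))
  npr <- spec$particles_per_ring
  r0 <- spec$ring_spacing
  R <- spec$inner_radius
  n_rings <- n_rings_over(spec$total_length, r0)
  n_dcm <- n_rings_over(spec$dcm_length, r0)

  # segment map for colon rings: seg k owns rings 4k-3..4k-1; ring 4k is the
  # shared boundary, belonging to neither neighbour (k < n_segments); rings
  # beyond n_dcm are tank wall.  For the published geometry the pattern
  # tiles the section exactly: 10 x 3 mobile + 9 boundary = 39 rings.
  seg_of_ring <- rep(NA_integer_, n_rings)
  kind_of_ring <- rep("tank_wall", n_rings)
  kind_of_ring[seq_len(min(n_dcm, n_rings))] <- "membrane"
  for (k in seq_len(spec$n_segments)) {
    rr <- (4 * k - 3):(4 * k - 1)
    rr <- rr[rr <= n_dcm]
    seg_of_ring[rr] <- k
  }

  one_layer <- function(radius, theta0, x_offset, n_r, layer) {
    theta <- theta0 + 2 * pi * (seq_len(npr) - 1) / npr
    fixed_az <- (c(90, 210, 330) * pi / 180)[seq_len(spec$n_fixed_rows)]
    fixed_idx <- vapply(fixed_az, function(a) {
      d <- abs(atan2(sin(theta - a), cos(theta - a)))
      which.min(d)
    }, integer(1))
    if (anyDuplicated(fixed_idx))
      abort("rings cannot host 3 distinct fixed rows")
    ring <- rep(seq_len(n_r), each = npr)
    in_dcm <- kind_of_ring[ring] == "membrane"
    kind <- ifelse(in_dcm, "membrane_mobile", "tank_wall")
    is_fixed <- in_dcm & (rep(seq_len(npr), n_r) %in% fixed_idx)
    kind[is_fixed] <- "membrane_fixed"
    tibble(
      id = NA_integer_, kind = kind, layer = layer, ring = ring,
      segment = ifelse(in_dcm, seg_of_ring[ring], NA_integer_) |>
        as.integer(),
      x = (ring - 1) * r0 + x_offset,
      y = rep(radius * cos(theta), n_r),
      z = rep(radius * sin(theta), n_r),
      vx = 0, vy = 0, vz = 0,
      mass = spec$membrane_particle_mass,
      density = NA_real_)
  }

  out <- one_layer(R, 0, 0, n_rings, 1L)
  if (layers == 2L) {
    gap_az <- 2 * pi * R / npr
    outer <- one_layer(R + 0.5 * gap_az, pi / npr, 0.5 * r0, n_rings - 1, 2L)
    out <- bind_rows(out, outer)
  }
  out$id <- seq_len(nrow(out))
  out
}

#' Fill the lumen with fluid particles
#'
#' Fluid particles are placed on a simple cubic lattice inside the neutral
#' lumen of the colon section (radial clearance of half a lattice spacing
#' from the wall) and taken bottom-up in `z` until the summed particle volume
#' `n * mass / density` matches the requested volume; the gas space above is
#' left empty.
#'
#' @param spec A [geometry_spec()].
#' @param fill A [fill_spec()].
#' @return A tibble of fluid particles (same columns as [build_membrane()]).
#' @export
fill_fluid <- function(spec = geometry_spec(), fill = fill_spec()) {
  stopifnot(inherits(spec, "geometry_spec"), inherits(fill, "fill_spec"))
  dx <- fill$lattice_spacing
  cell <- fill$particle_mass / fill$density
  n_target <- round(fill$volume / cell)
  if (n_target < 1) n_target <- 1L

  # radial clearance of 0.45 spacings from the wall circle; the z lattice is
  # bottom-aligned so the lowest layer starts in contact range of the wall
  # instead of dropping onto it when gravity is switched on
  rmax <- spec$inner_radius - 0.45 * dx
  xs <- seq(dx / 2, spec$dcm_length - dx / 2, by = dx)
  ny <- floor(2 * rmax / dx) + 1
  ys <- (seq_len(ny) - (ny + 1) / 2) * dx
  zs <- seq(-rmax, rmax, by = dx)
  grid <- expand.grid(y = ys, z = zs)
  grid <- grid[grid$y^2 + grid$z^2 <= rmax^2 + 1e-12, ]
  capacity <- nrow(grid) * length(xs)
  if (n_target > capacity)
    abort(sprintf("requested volume %.1f mL exceeds lumen capacity %.1f mL",
                  fill$volume * 1e6, capacity * cell * 1e6))

  grid <- grid[order(grid$z, grid$y), ]
  # bottom-up: fill whole z-layers across all x, lowest first
  ord <- order(rep(grid$z, each = length(xs)))
  pts <- tibble(
    x = rep(xs, times = nrow(grid)),
    y = rep(grid$y, each = length(xs)),
    z = rep(grid$z, each = length(xs)))[ord, ][seq_len(n_target), ]

  tibble(
    id = seq_len(n_target),
    kind = "fluid", layer = 1L,
    ring = NA_integer_, segment = NA_integer_,
    x = pts$x, y = pts$y, z = pts$z,
    vx = 0, vy = 0, vz = 0,
    mass = fill$particle_mass,
    density = fill$density)
}

#' Occlusion degree of a membrane ring
#'
#' `100 * (neutral_radius - mean radius of the mobile ring particles) /
#' neutral_radius`; positive values are contraction, negative relaxation.
#'
#' @param ring_particles Data frame with `y`, `z` (and optionally `kind`;
#'   only `membrane_mobile` rows are used when present).
#' @param neutral_radius Neutral lumen radius (m).
#' @return Occlusion degree in percent.
#' @export
occlusion_degree <- function(ring_particles, neutral_radius) {
  p <- ring_particles
  if ("layer" %in% names(p)) p <- p[is.na(p$layer) | p$layer == 1, , drop = FALSE]
  if ("kind" %in% names(p)) p <- p[p$kind == "membrane_mobile", , drop = FALSE]
  if (nrow(p) == 0) abort("ring has no mobile particles")
  100 * (neutral_radius - mean(sqrt(p$y^2 + p$z^2))) / neutral_radius
}

#' Assemble the full simulation domain
#'
#' Combines the membrane/tank shell, the end constriction (two rings of
#' static particles at reduced radius at the colon/tank junction) and the
#' fluid fill into one particle table, and attaches the spring network.
#'
#' @param spec A [geometry_spec()].
#' @param fill A [fill_spec()], or `NULL` for a dry domain.
#' @param network_pars List of membrane lattice constants `k_bond`,
#'   `k_tether`, `k_damp` (see [spring_network()]).
#' @param membrane_layers Number of membrane layers (2 closes the shell's
#'   lattice gap channels; see [build_membrane()]).
#' @return A `dcm_domain` list: `particles` (tibble), `network`, `spec`,
#'   `fill`.
#' @export
build_domain <- function(spec = geometry_spec(), fill = fill_spec(),
                         network_pars = list(), membrane_layers = 2L) {
  shell <- build_membrane(spec, layers = membrane_layers)

  # end constriction: 2 rings at reduced radius at the colon/tank junction
  npr <- spec$particles_per_ring
  theta <- 2 * pi * (seq_len(npr) - 1) / npr
  rcon <- spec$constriction_radius_fraction * spec$inner_radius
  con <- tibble(
    id = NA_integer_, kind = "tank_wall", layer = 1L, ring = NA_integer_,
    segment = NA_integer_,
    x = rep(spec$dcm_length + c(0, spec$ring_spacing), each = npr),
    y = rep(rcon * cos(theta), 2), z = rep(rcon * sin(theta), 2),
    vx = 0, vy = 0, vz = 0,
    mass = spec$membrane_particle_mass, density = NA_real_)

  # end caps close the tube (the physical device is sealed at both ends);
  # one lattice layer of static wall just outside each end plane
  cap_s <- if (!is.null(fill)) min(fill$lattice_spacing, 5e-3) else 5e-3
  nc <- floor(2 * (spec$inner_radius - 0.25 * cap_s) / cap_s)
  yzc <- (seq_len(nc) - (nc + 1) / 2) * cap_s
  gc <- expand.grid(y = yzc, z = yzc)
  gc <- gc[gc$y^2 + gc$z^2 <= (spec$inner_radius - 0.25 * cap_s)^2, ]
  caps <- tibble(
    id = NA_integer_, kind = "tank_wall", layer = 1L, ring = NA_integer_,
    segment = NA_integer_,
    x = rep(c(-0.5 * cap_s, spec$total_length + 0.5 * cap_s),
            each = nrow(gc)),
    y = rep(gc$y, 2), z = rep(gc$z, 2),
    vx = 0, vy = 0, vz = 0,
    mass = (if (!is.null(fill)) fill$density else 1017) * cap_s^3,
    density = NA_real_)

  fluid <- if (!is.null(fill)) fill_fluid(spec, fill) else NULL
  particles <- bind_rows(shell, con, caps, fluid)
  particles$id <- seq_len(nrow(particles))
  rho0 <- if (!is.null(fill)) fill$density else 1017
  particles$density[is.na(particles$density)] <- rho0

  check_overlaps(particles, if (!is.null(fill)) fill$lattice_spacing else spec$ring_spacing)

  network <- do.call(spring_network, c(list(particles = particles, spec = spec),
                                       network_pars))
  structure(list(particles = particles, network = network,
                 spec = spec, fill = fill),
            class = "dcm_domain")
}

# reject particle tables with near-coincident points (closer than 0.1 dx)
check_overlaps <- function(particles, dx) {
  tol <- 0.1 * dx
  key <- paste(round(particles$x / tol), round(particles$y / tol),
               round(particles$z / tol))
  dup <- duplicated(key)
  if (any(dup)) {
    i <- which(dup)[1]
    j <- which(key == key[i])[1]
    d <- sqrt((particles$x[i] - particles$x[j])^2 +
              (particles$y[i] - particles$y[j])^2 +
              (particles$z[i] - particles$z[j])^2)
    if (d < tol) abort(sprintf(
      "overlapping particles %d and %d (distance %.2e < %.2e m)", j, i, d, tol))
  }
  invisible(particles)
}

#' @export
print.dcm_domain <- function(x, ...) {
  tab <- table(x$particles$kind)
  cat("<dcm_domain> ", nrow(x$particles), " particles\n", sep = "")
  for (k in names(tab)) cat(sprintf("  %-16s %d\n", k, tab[[k]]))
  cat("  bonds:", length(x$network$bond_i), " tethers on mobile membrane\n")
  invisible(x)
}

#' Write particles as an extended-XYZ snapshot
#'
#' Plain-text export with per-particle kind, segment and density, readable by
#' OVITO and similar viewers.
#'
#' @param particles Particle tibble.
#' @param path Output file.
#' @param comment Comment line.
#' @export
write_xyz <- function(particles, path, comment = "dcmtwin snapshot") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(particles)), con)
  writeLines(comment, con)
  writeLines(sprintf("%s %.8e %.8e %.8e %.6e %d",
                     particles$kind, particles$x, particles$y, particles$z,
                     particles$density,
                     ifelse(is.na(particles$segment), 0L, particles$segment)),
             con)
  invisible(path)
}
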