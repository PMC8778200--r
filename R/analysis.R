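#' Rasterise a cross-sectional slice into a pixel grid
#'
#' Phase-contrast-style analysis grid: streamwise velocity `v_x` of every
#' pixel is the mass-weighted mean over fluid particles whose (y, z)
#' projection falls in the pixel's square and whose x lies within the slab.
#' Empty in-lumen pixels are filled from their populated neighbours within
#' one pixel, otherwise masked. The per-pixel flow rate is `q = v_x L^2`.
#'
#' @param particles Particle tibble (a snapshot).
#' @param x_plane Slice location (m).
#' @param L Pixel edge length (m); 1.1e-3 mirrors the MRI recon resolution.
#' @param slab Slab (slice) thickness (m).
#' @param lumen_radius Radius of the in-lumen mask circle (m).
#' @return A `pixel_grid` tibble: `iy`, `iz`, `y`, `z`, `vx`, `q`,
#'   `in_lumen`, `masked`; attributes `L`, `slab`, `x_plane`, `ny`, `nz`.
#' @export
rasterize_slice <- function(particles, x_plane, L = 1.1e-3, slab = 8e-3,
                            lumen_radius = 0.02) {
  stopifnot(L > 0, slab > 0)
  fl <- particles[particles$kind == "fluid" &
                  abs(particles$x - x_plane) <= slab / 2, ]
  half <- ceiling(lumen_radius / L - 0.5)
  centers <- (-half:half) * L
  ny <- nz <- length(centers)
  grid <- expand.grid(iy = seq_len(ny), iz = seq_len(nz))
  grid$y <- centers[grid$iy]
  grid$z <- centers[grid$iz]
  grid$in_lumen <- grid$y^2 + grid$z^2 <= lumen_radius^2

  vx <- rep(NA_real_, nrow(grid))
  if (nrow(fl) > 0) {
    piy <- round(fl$y / L) + half + 1
    piz <- round(fl$z / L) + half + 1
    ok <- piy >= 1 & piy <= ny & piz >= 1 & piz <= nz
    cell <- piy[ok] + ny * (piz[ok] - 1)
    wsum <- tapply_add(fl$mass[ok], cell, ny * nz)
    vsum <- tapply_add(fl$mass[ok] * fl$vx[ok], cell, ny * nz)
    vx <- ifelse(wsum > 0, vsum / wsum, NA_real_)
  }
  # fill empty in-lumen pixels from populated neighbours within one pixel
  m <- matrix(vx, ny, nz)
  empty <- is.na(m) & matrix(grid$in_lumen, ny, nz)
  if (any(empty)) {
    filled <- m
    for (idx in which(empty)) {
      iy <- (idx - 1) %% ny + 1
      iz <- (idx - 1) %/% ny + 1
      ys <- max(1, iy - 1):min(ny, iy + 1)
      zs <- max(1, iz - 1):min(nz, iz + 1)
      nb <- m[ys, zs]
      if (any(!is.na(nb))) filled[idx] <- mean(nb, na.rm = TRUE)
    }
    m <- filled
  }
  grid$vx <- as.vector(m)
  grid$masked <- !grid$in_lumen | is.na(grid$vx)
  grid$vx[!grid$in_lumen] <- NA_real_
  grid$q <- grid$vx * L^2
  out <- as_tibble(grid[, c("iy", "iz", "y", "z", "vx", "q",
                            "in_lumen", "masked")])
  attr(out, "L") <- L
  attr(out, "slab") <- slab
  attr(out, "x_plane") <- x_plane
  attr(out, "ny") <- ny
  attr(out, "nz") <- nz
  class(out) <- c("pixel_grid", class(out))
  out
}

#' Shear-rate maps on a pixel grid
#'
#' Central differences of `v_x` along y and z via a 3-point stencil; the
#' `"standard"` dialect divides the 2-pixel-span difference by `2L` (exact
#' on linear fields), the `"as_printed"` dialect divides by `L` (and so
#' returns exactly twice the gradient of a linear field). Pixels adjacent
#' to the mask use one-sided differences. The combined map is the Frobenius
#' norm `sqrt(gamma_y^2 + gamma_z^2)`.
#'
#' @param grid A [rasterize_slice()] result.
#' @param dialect `"standard"` or `"as_printed"`.
#' @return The grid with `gamma_y`, `gamma_z`, `gamma_norm` columns (s^-1).
#' @export
pixel_shear_map <- function(grid, dialect = c("standard", "as_printed")) {
  dialect <- match.arg(dialect)
  L <- attr(grid, "L")
  ny <- attr(grid, "ny"); nz <- attr(grid, "nz")
  den <- if (dialect == "standard") 2 * L else L
  v <- matrix(grid$vx, ny, nz)
  v[matrix(grid$masked, ny, nz)] <- NA

  diff_along <- function(v, dim) {
    n <- dim(v)[dim]
    shift <- function(k) {
      out <- v * NA
      src <- seq_len(n) + k
      keep <- src >= 1 & src <= n
      if (dim == 1) out[keep, ] <- v[src[keep], , drop = FALSE]
      else out[, keep] <- v[, src[keep], drop = FALSE]
      out
    }
    vp <- shift(1); vm <- shift(-1)
    g_c <- (vp - vm) / den                     # central, 2-pixel span
    g_f <- (vp - v) / L                        # one-sided fallbacks
    g_b <- (v - vm) / L
    out <- g_c
    use_f <- is.na(vm) & !is.na(vp)
    use_b <- is.na(vp) & !is.na(vm)
    out[use_f] <- g_f[use_f]
    out[use_b] <- g_b[use_b]
    out[is.na(v)] <- NA
    out
  }
  gy <- diff_along(v, 1)
  gz <- diff_along(v, 2)
  grid$gamma_y <- as.vector(gy)
  grid$gamma_z <- as.vector(gz)
  grid$gamma_norm <- sqrt(grid$gamma_y^2 + grid$gamma_z^2)
  attr(grid, "dialect") <- dialect
  grid
}

#' Per-particle shear rate from the reduced stress tensor
#'
#' SPH (kernel-weighted, difference-form) estimate of the streamwise
#' velocity gradient at each fluid particle, with wall particles
#' contributing their own velocity (no-slip). Only the yx and zx stress
#' components survive the streamwise-velocity reduction:
#' `tau_yx = eta dvx/dy`, `tau_zx = eta dvx/dz`, combined by Frobenius
#' norm, and `gamma_dot = |tau| / eta`.
#'
#' @param particles Particle tibble (a snapshot).
#' @param viscosity Dynamic viscosity eta (Pa s).
#' @param h Smoothing length for the gradient estimator (m).
#' @return Tibble `id`, `dvx_dy`, `dvx_dz`, `tau_yx`, `tau_zx`, `tau_norm`,
#'   `gamma_dot` for fluid particles.
#' @export
particle_shear_rate <- function(particles, viscosity, h) {
  stopifnot(viscosity > 0, h > 0)
  st <- particles_to_cpp(particles)
  g <- cpp_grad_vx(st$pos, particles$vx, st$mass, st$dens, st$kind, h)
  fl <- particles$kind == "fluid"
  tau_yx <- viscosity * g[fl, 1]
  tau_zx <- viscosity * g[fl, 2]
  tau_norm <- sqrt(tau_yx^2 + tau_zx^2)
  tibble(id = particles$id[fl],
         dvx_dy = g[fl, 1], dvx_dz = g[fl, 2],
         tau_yx = tau_yx, tau_zx = tau_zx,
         tau_norm = tau_norm, gamma_dot = tau_norm / viscosity)
}

#' Cross-section velocity series at a slice
#'
#' At each snapshot: mean streamwise velocity over fluid particles in the
#' slab; central-peak velocity (mean over the central disc of radius
#' `1.25 L` around the lumen axis — the 5-central-pixel analogue); top-4
#' peak (mean of the 4 highest pixel values after rasterisation); and the
#' occlusion degree of the membrane ring nearest the slice. Empty slabs
#' yield missing values.
#'
#' @param sim A `dmp_sim` from [simulate_particles()].
#' @param x_plane Slice location (m).
#' @param spec The [geometry_spec()] of the domain.
#' @param slab Slab thickness (m).
#' @param L Pixel size for the rasterised statistics (m); defaults to the
#'   MRI-like 1.1e-3 or half the fluid lattice spacing, whichever is larger.
#' @return Tibble `time`, `mean_vx`, `central_vx`, `top4_vx`, `occlusion`,
#'   `n_particles`.
#' @export
cross_section_series <- function(sim, x_plane, spec = geometry_spec(),
                                 slab = 8e-3, L = NULL) {
  dx <- sim$params$lattice_spacing %||% 2.351e-3
  L <- L %||% max(1.1e-3, dx / 2)
  p0 <- sim$particles0
  lay1 <- (p0$layer %||% 1L) == 1L
  ring_x <- (sort(unique(p0$ring[!is.na(p0$ring)])) - 1) * spec$ring_spacing
  near_ring <- which.min(abs(ring_x - x_plane))
  ring_rows <- which(p0$kind == "membrane_mobile" & p0$ring == near_ring & lay1)

  rows <- lapply(sim$snapshots, function(sn) {
    p <- sim$particles0
    p$x <- sn$pos[, 1]; p$y <- sn$pos[, 2]; p$z <- sn$pos[, 3]
    p$vx <- sn$vel[, 1]
    fl <- p$kind == "fluid" & abs(p$x - x_plane) <= slab / 2
    occ <- if (length(ring_rows)) {
      100 * (spec$inner_radius -
             mean(sqrt(sn$pos[ring_rows, 2]^2 + sn$pos[ring_rows, 3]^2))) /
        spec$inner_radius
    } else NA_real_
    if (!any(fl)) {
      return(tibble(time = sn$time, mean_vx = NA_real_, central_vx = NA_real_,
                    top4_vx = NA_real_, occlusion = occ, n_particles = 0L))
    }
    pf <- p[fl, ]
    central <- pf$y^2 + pf$z^2 <= (1.25 * L)^2
    gridded <- rasterize_slice(p[p$kind == "fluid", ], x_plane, L = L,
                               slab = slab, lumen_radius = spec$inner_radius)
    vals <- gridded$vx[!gridded$masked]
    top4 <- if (length(vals) >= 1) mean(sort(vals, decreasing = TRUE)[
      seq_len(min(4, length(vals)))]) else NA_real_
    tibble(time = sn$time,
           mean_vx = mean(pf$vx),
           central_vx = if (any(central)) mean(pf$vx[central]) else NA_real_,
           top4_vx = top4, occlusion = occ, n_particles = sum(fl))
  })
  out <- bind_rows(rows)
  class(out) <- c("dcm_series", class(out))
  attr(out, "x_plane") <- x_plane
  out
}

#' Bottom-wall shear-rate series
#'
#' At each snapshot, the mean and maximum particle shear rate over the
#' lower layer of fluid closest to the bottom wall: fluid particles within
#' one smoothing length of the lowest fluid in a segment's axial window
#' (anchoring at the fluid's own bottom keeps the layer populated despite
#' the contact standoff of coarse lattices). An empty window yields missing
#' values.
#'
#' @param sim A `dmp_sim`.
#' @param window Axial window `c(x0, x1)` (m), e.g. segment 6 is
#'   `c(0.120, 0.144)`.
#' @param viscosity Dynamic viscosity (Pa s).
#' @param h Wall-layer thickness (m); defaults to the run's smoothing
#'   length.
#' @param grad_h Smoothing length of the shear-rate estimator (m). Defaults
#'   to the full-resolution measurement scale (4.71e-3 m) floored at 1.5
#'   lattice spacings (kernel support for the corrected gradient): the
#'   estimator scale belongs to the measurement definition, so coarsening
#'   the solver does not coarsen it more than the lattice forces.
#' @param segment Optional label carried through to the output.
#' @return Tibble `time`, `mean_shear`, `max_shear`, `n_layer`, `segment`.
#' @export
bottom_wall_shear_series <- function(sim, window, viscosity,
                                     h = sim$params$h,
                                     grad_h = NULL, segment = NA) {
  dx <- sim$params$lattice_spacing %||% 2.351e-3
  grad_h <- grad_h %||% max(4.71e-3, 1.5 * dx)
  rows <- lapply(sim$snapshots, function(sn) {
    p <- sim$particles0
    p$x <- sn$pos[, 1]; p$y <- sn$pos[, 2]; p$z <- sn$pos[, 3]
    p$vx <- sn$vel[, 1]; p$density <- sn$dens
    in_win <- p$kind == "fluid" & p$x >= window[1] & p$x <= window[2]
    if (!any(in_win)) {
      return(tibble(time = sn$time, mean_shear = NA_real_,
                    max_shear = NA_real_, n_layer = 0L))
    }
    z_ref <- min(p$z[in_win])
    layer <- in_win & p$z <= z_ref + h
    if (!any(layer)) {
      return(tibble(time = sn$time, mean_shear = NA_real_,
                    max_shear = NA_real_, n_layer = 0L))
    }
    sr <- particle_shear_rate(p, viscosity, grad_h)
    gd <- sr$gamma_dot[match(p$id[layer], sr$id)]
    tibble(time = sn$time, mean_shear = mean(gd), max_shear = max(gd),
           n_layer = sum(layer))
  })
  out <- bind_rows(rows)
  out$segment <- segment
  class(out) <- c("shear_series", class(out))
  out
}

#' Total sum of squared differences between two series
#'
#' The series are linearly interpolated onto a common time grid — the grid
#' of the coarser series, restricted to the overlap of their supports —
#' and the squared differences are summed.
#'
#' @param series_a,series_b Data frames with `time` and a value column.
#' @param value Name of the value column.
#' @return TSS (scalar, >= 0).
#' @export
tss <- function(series_a, series_b, value = "value") {
  ta <- series_a$time; tb <- series_b$time
  va <- series_a[[value]]; vb <- series_b[[value]]
  lo <- max(min(ta), min(tb))
  hi <- min(max(ta), max(tb))
  if (lo > hi) abort("disjoint time supports")
  # common grid: the coarser series' own samples within the overlap
  grid <- if (length(ta) <= length(tb)) ta else tb
  grid <- grid[grid >= lo & grid <= hi]
  ya <- approx(ta, va, xout = grid)$y
  yb <- approx(tb, vb, xout = grid)$y
  sum((ya - yb)^2)
}

#' Main effects of a two-level full factorial
#'
#' For each factor: the mean response at its high level minus the mean at
#' its low level (over the 2^3 design that is 4 runs per level), with a
#' two-sample Welch t-test at each factor.
#'
#' @param results Data frame with one row per run: the factor columns and a
#'   response column.
#' @param response Name of the response column.
#' @param factors Names of the (two-level) factor columns.
#' @return A `main_effects` tibble: `factor`, `low`, `high`, `low_mean`,
#'   `high_mean`, `effect`, `p_value`.
#' @export
main_effects <- function(results,
                         response = "peak_mean_shear",
                         factors = c("wave_speed", "viscosity", "volume")) {
  for (f in factors) {
    if (length(unique(results[[f]])) != 2)
      abort(sprintf("factor `%s` must have exactly 2 levels", f))
  }
  combos <- do.call(paste, c(results[factors], sep = "/"))
  if (length(unique(combos)) != 2^length(factors))
    abort("incomplete factorial: every factor-level combination must be present")
  y <- results[[response]]
  rows <- lapply(factors, function(f) {
    lv <- sort(unique(results[[f]]))
    ylo <- y[results[[f]] == lv[1]]
    yhi <- y[results[[f]] == lv[2]]
    p <- if (stats::var(ylo) + stats::var(yhi) > 0) {
      t.test(yhi, ylo, var.equal = FALSE)$p.value
    } else if (mean(yhi) == mean(ylo)) 1 else 0
    tibble(factor = f,
           low = as.character(lv[1]), high = as.character(lv[2]),
           low_mean = mean(ylo), high_mean = mean(yhi),
           effect = mean(yhi) - mean(ylo), p_value = p)
  })
  out <- bind_rows(rows)
  class(out) <- c("main_effects", class(out))
  attr(out, "response") <- response
  out
}

#' @rdname main_effects
#' @param x A `main_effects` table.
#' @param ... Unused.
#' @export
tidy.main_effects <- function(x, ...) {
  as_tibble(unclass(x))
}
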