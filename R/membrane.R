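#' Build the membrane spring network
#'
#' Bonds connect azimuthal neighbours within a ring, axial neighbours between
#' adjacent rings, and both diagonal neighbours, over all rings of the colon
#' section (equivalent to a proximity rule with cut-off 1.5 x the largest
#' build spacing on this lattice). Each bond stores its actual build-time
#' length as equilibrium length. Every membrane particle is tethered to its
#' build position.
#'
#' @param particles Particle tibble from [build_membrane()] or
#'   [build_domain()].
#' @param spec The [geometry_spec()] used to build it.
#' @param k_bond Hookean bond stiffness (J m^-2).
#' @param k_tether Tether stiffness toward the build anchor (J m^-2).
#' @param k_damp Viscous damping coefficient (kg s^-1).
#' @return A `spring_network` list: `bond_i`, `bond_j`, `bond_l0`, the three
#'   constants, and an `anchors` matrix (one row per particle).
#' @export
spring_network <- function(particles, spec, k_bond = 0.1, k_tether = 0.012,
                           k_damp = 1.0e-2) {
  stopifnot(k_bond >= 0, k_tether >= 0, k_damp >= 0)
  npr <- spec$particles_per_ring
  layer <- particles$layer %||% rep(1L, nrow(particles))
  is_memb <- particles$kind %in% c("membrane_mobile", "membrane_fixed")

  nxt <- function(s) s %% npr + 1L
  lattice_bonds <- function(memb) {
    rings <- sort(unique(particles$ring[memb]))
    az_slot <- integer(nrow(particles))
    for (r in rings) {
      rows <- memb[particles$ring[memb] == r]
      th <- atan2(particles$z[rows], particles$y[rows])
      az_slot[rows] <- rank(th)
    }
    idx <- matrix(NA_integer_, nrow = max(rings), ncol = npr)
    idx[cbind(particles$ring[memb], az_slot[memb])] <- memb
    bi <- integer(0); bj <- integer(0)
    for (r in rings) {
      for (s in seq_len(npr)) {
        i <- idx[r, s]
        bi <- c(bi, i); bj <- c(bj, idx[r, nxt(s)])      # azimuthal
        if ((r + 1) %in% rings) {                        # axial + diagonals
          bi <- c(bi, i, i, idx[r, nxt(s)])
          bj <- c(bj, idx[r + 1, s], idx[r + 1, nxt(s)], idx[r + 1, s])
        }
      }
    }
    list(bi = bi, bj = bj)
  }

  memb1 <- which(is_memb & layer == 1L)
  b <- lattice_bonds(memb1)
  bi <- b$bi; bj <- b$bj

  # the last membrane ring is tied axially (one bond per particle) to the
  # adjacent static tank ring: the physical tube continues past the actuated
  # section, so the end segment is not a free edge, but a full lattice
  # connection would over-restrain it relative to the interior segments
  last_ring <- max(particles$ring[memb1])
  endm <- memb1[particles$ring[memb1] == last_ring]
  for (i in endm) {
    cand <- which(layer == 1L & particles$kind == "tank_wall" &
                  particles$ring %in% (last_ring + 1L))
    if (!length(cand)) break
    d2 <- (particles$x[cand] - particles$x[i])^2 +
      (particles$y[cand] - particles$y[i])^2 +
      (particles$z[cand] - particles$z[i])^2
    bi <- c(bi, i); bj <- c(bj, cand[which.min(d2)])
  }

  memb2 <- which(is_memb & layer == 2L)
  if (length(memb2)) {
    b2 <- lattice_bonds(memb2)
    bi <- c(bi, b2$bi); bj <- c(bj, b2$bj)
    # cross-layer bonds: each outer particle to its 4 nearest inner
    # particles (the staggered cage sits between inner rings j and j+1)
    for (i in memb2) {
      cand <- memb1[particles$ring[memb1] %in%
                    (particles$ring[i] + c(0L, 1L))]
      d2 <- (particles$x[cand] - particles$x[i])^2 +
        (particles$y[cand] - particles$y[i])^2 +
        (particles$z[cand] - particles$z[i])^2
      near <- cand[order(d2)[seq_len(min(4, length(cand)))]]
      bi <- c(bi, rep(i, length(near))); bj <- c(bj, near)
    }
  }

  l0 <- sqrt((particles$x[bi] - particles$x[bj])^2 +
             (particles$y[bi] - particles$y[bj])^2 +
             (particles$z[bi] - particles$z[bj])^2)
  structure(
    list(bond_i = bi, bond_j = bj, bond_l0 = l0,
         k_bond = k_bond, k_tether = k_tether, k_damp = k_damp,
         anchors = as.matrix(particles[, c("x", "y", "z")])),
    class = "spring_network")
}

#' Hookean bond and tether forces
#'
#' Evaluates `F_ij = k (r_ij - r0)` along each bond (equal and opposite on
#' the pair) plus the tether force `k_tether (anchor - r_i)` on mobile
#' membrane particles. Damping is not included (see [damping_force()]).
#'
#' @param network A [spring_network()].
#' @param particles Particle tibble with current positions.
#' @return Matrix (n x 3) of forces in N.
#' @export
hookean_forces <- function(network, particles) {
  n <- nrow(particles)
  f <- matrix(0, n, 3)
  pos <- as.matrix(particles[, c("x", "y", "z")])
  d <- pos[network$bond_j, , drop = FALSE] - pos[network$bond_i, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  zero <- r < 1e-12
  if (any(zero)) {
    warn("coincident bonded particles; their bond force set to 0")
    r[zero] <- 1
    d[zero, ] <- 0
  }
  fb <- network$k_bond * (r - network$bond_l0) / r
  fb[zero] <- 0
  for (c in 1:3) {
    f[, c] <- f[, c] +
      tapply_add(fb * d[, c], network$bond_i, n) -
      tapply_add(fb * d[, c], network$bond_j, n)
  }
  mob <- particles$kind == "membrane_mobile"
  f[mob, ] <- f[mob, ] +
    network$k_tether * (network$anchors[mob, , drop = FALSE] - pos[mob, , drop = FALSE])
  f
}

tapply_add <- function(vals, idx, n) {
  out <- numeric(n)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Viscous damping force on a membrane particle
#'
#' `F = -k_damp v`; always dissipative.
#'
#' @param k_damp Damping coefficient (kg s^-1).
#' @param velocity Velocity vector(s): length-3 vector or n x 3 matrix.
#' @return Force of the same shape (N).
#' @export
damping_force <- function(k_damp, velocity) -k_damp * velocity

#' Propagating-pressure-wave motility program
#'
#' Encodes the per-segment radial force schedule of one antegrade peristaltic
#' wave. Segment k activates at offset `(k - 1) * segment_length /
#' wave_speed`; its cycle is an outward (relaxation) phase, an inward
#' (contraction) phase, then a longer taper of the inward force so the
#' tethers restore the neutral position more slowly than contraction built
#' up — the phase fractions are multiples of the segment period
#' `segment_length / wave_speed`.
#'
#' @param wave_speed Wave propagation speed (m s^-1): 0.004 (slow) or 0.008
#'   (fast).
#' @param occlusion_target Peak occlusion degree aimed for (%).
#' @param relaxation_target Relaxation occlusion aimed for (%; negative).
#' @param f_relax,f_contract,f_return Phase durations as fractions of the
#'   segment period.
#' @param amp_contract,amp_relax Radial force amplitudes (N per particle);
#'   `NULL` until set by [calibrate_occlusion()].
#' @param dcm_length,n_segments Geometry of the actuated section.
#' @return A `motility_program` list with derived `segment_length`,
#'   `segment_period` and `offsets`.
#' @export
motility_program <- function(wave_speed = 0.004, occlusion_target = 60,
                             relaxation_target = -20,
                             f_relax = 0.3, f_contract = 0.3, f_return = 1.4,
                             amp_contract = NULL, amp_relax = NULL,
                             dcm_length = 0.24, n_segments = 10L) {
  if (f_return <= f_contract)
    abort("slow-return phase must be longer than the contraction phase")
  seg_len <- dcm_length / n_segments
  period <- seg_len / wave_speed
  structure(
    list(wave_speed = wave_speed, occlusion_target = occlusion_target,
         relaxation_target = relaxation_target,
         f_relax = f_relax, f_contract = f_contract, f_return = f_return,
         amp_contract = amp_contract, amp_relax = amp_relax,
         dcm_length = dcm_length, n_segments = as.integer(n_segments),
         segment_length = seg_len, segment_period = period,
         offsets = (seq_len(n_segments) - 1) * period),
    class = "motility_program")
}

#' Time for the wave to traverse the actuated section
#' @param program A [motility_program()].
#' @return Traversal time `dcm_length / wave_speed` in seconds.
#' @export
wave_traversal_time <- function(program) program$dcm_length / program$wave_speed

#' Total duration of one wave including the final segment's slow return
#' @param program A [motility_program()].
#' @return Duration in seconds.
#' @export
wave_duration <- function(program) {
  program$offsets[program$n_segments] +
    (program$f_relax + program$f_contract + program$f_return) * program$segment_period
}

#' Signed radial motility force for one segment
#'
#' Piecewise schedule: zero before the segment's offset, `-amp_relax`
#' (outward) during initial relaxation, `+amp_contract` (inward) during
#' contraction, then a linear taper of the inward force over the slow-return
#' phase, and zero afterwards. Positive values point toward the tube axis.
#'
#' @param program A [motility_program()] with amplitudes set.
#' @param segment Segment index (1-based).
#' @param t Time(s) since wave start (s); vectorised.
#' @return Signed force magnitude(s) in N per mobile particle.
#' @export
motility_force <- function(program, segment, t) {
  stopifnot(segment >= 1, segment <= program$n_segments)
  amp_c <- program$amp_contract %||% 0
  amp_r <- program$amp_relax %||% 0
  T <- program$segment_period
  ph <- t - program$offsets[segment]
  t1 <- program$f_relax * T
  t2 <- t1 + program$f_contract * T
  t3 <- t2 + program$f_return * T
  out <- numeric(length(ph))
  out[ph >= 0 & ph < t1] <- -amp_r
  out[ph >= t1 & ph < t2] <- amp_c
  ret <- ph >= t2 & ph < t3
  out[ret] <- amp_c * (1 - (ph[ret] - t2) / (t3 - t2))
  out
}

# pack a motility program for the C++ core
motility_cpp <- function(program = NULL, only_segment = -1L) {
  if (is.null(program)) return(list(on = FALSE))
  list(on = TRUE,
       amp_contract = program$amp_contract %||% 0,
       amp_relax = program$amp_relax %||% 0,
       segment_period = program$segment_period,
       f_relax = program$f_relax, f_contract = program$f_contract,
       f_return = program$f_return,
       only_segment = as.integer(only_segment))
}

#' Wall-displacement (occlusion) series from a simulation
#'
#' Occlusion degree of the middle ring of each requested segment at every
#' snapshot.
#'
#' @param sim A simulation result from [simulate_particles()].
#' @param spec The [geometry_spec()] of the domain.
#' @param segments Segment indices to report.
#' @return Tibble `time`, `segment`, `occlusion`.
#' @export
wall_displacement_series <- function(sim, spec, segments = c(2, 6, 10)) {
  p0 <- sim$particles0
  lay1 <- is.na(p0$layer %||% NA) | (p0$layer %||% 1L) == 1L
  rows <- lapply(segments, function(s) {
    mid_ring <- 4 * s - 2
    which(p0$kind == "membrane_mobile" & p0$ring == mid_ring & lay1)
  })
  out <- lapply(seq_along(sim$snapshots), function(k) {
    sn <- sim$snapshots[[k]]
    tibble(time = sn$time, segment = segments,
           occlusion = vapply(rows, function(r) {
             100 * (spec$inner_radius -
                    mean(sqrt(sn$pos[r, 2]^2 + sn$pos[r, 3]^2))) /
               spec$inner_radius
           }, numeric(1)))
  })
  bind_rows(out)
}

#' Calibrate the motility force amplitudes to the occlusion targets
#'
#' Bisection on the radial force amplitude in a single-activated-segment dry
#' membrane domain until the peak occlusion degree matches the program's
#' contraction target, and likewise for the relaxation amplitude against the
#' relaxation target. Monotonicity of occlusion in amplitude is asserted over
#' the bracketing range as the search proceeds.
#'
#' @param program A [motility_program()].
#' @param spec A [geometry_spec()].
#' @param segment Segment to activate for the test (an interior segment by
#'   default).
#' @param dt Time step for the dry membrane runs (s).
#' @param tol Convergence tolerance on the occlusion degree (%).
#' @param max_iter Bisection iteration cap; exceeded brackets raise an error.
#' @return The program with `amp_contract`/`amp_relax` set, and attributes
#'   `calibration` (tibble of probed amplitudes) and `achieved` (peak and
#'   relaxation occlusion on replay).
#' @export
calibrate_occlusion <- function(program, spec = geometry_spec(), segment = 2L,
                                dt = 2.5e-3, tol = 0.5, max_iter = 50L) {
  domain <- build_domain(spec, fill = NULL)
  params <- sph_params(resolution = 1, rho0 = 1017, lattice_spacing = NULL)
  T <- program$segment_period
  mid_ring <- 4 * segment - 2
  rows <- which(domain$particles$kind == "membrane_mobile" &
                domain$particles$ring == mid_ring &
                domain$particles$layer == 1L)

  occ_series <- function(prog, t_end) {
    # t_end is measured from the segment's activation offset
    sim <- simulate_particles(domain$particles, params,
                              network = domain$network, program = prog,
                              only_segment = segment,
                              duration = prog$offsets[segment] + t_end, dt = dt,
                              snapshot_every = max(dt, T / 120))
    vapply(sim$snapshots, function(sn) {
      100 * (spec$inner_radius -
             mean(sqrt(sn$pos[rows, 2]^2 + sn$pos[rows, 3]^2))) /
        spec$inner_radius
    }, numeric(1))
  }

  bisect_amp <- function(measure, target, hi0 = 2e-3) {
    # measure(amp) must be nondecreasing in amp; expand then bisect
    probes <- list()
    f <- function(a) {
      v <- measure(a)
      probes[[length(probes) + 1]] <<- c(amp = a, occ = v)
      v
    }
    lo <- 0; flo <- f(0)
    hi <- hi0; fhi <- f(hi)
    it <- 0
    while (fhi < target && it < max_iter) { hi <- hi * 2; fhi <- f(hi); it <- it + 1 }
    if (fhi < target) abort("calibration failure: amplitude bracket not found")
    while (it < max_iter) {
      mid <- 0.5 * (lo + hi)
      fm <- f(mid)
      if (abs(fm - target) < tol) {
        tr <- do.call(rbind, probes)
        tr <- tr[order(tr[, "amp"]), , drop = FALSE]
        if (any(diff(tr[, "occ"]) < -tol))
          warn("occlusion response not monotone in amplitude over the bracket")
        return(list(amp = mid, trace = as_tibble(as.data.frame(tr))))
      }
      if (fm < target) { lo <- mid } else { hi <- mid }
      it <- it + 1
    }
    abort("calibration failure: bisection did not converge")
  }

  # contraction amplitude: peak occlusion over relax + contraction phases
  t_peak <- (program$f_relax + program$f_contract + 0.1) * T
  prog_c <- program
  prog_c$amp_relax <- 0
  cal_c <- bisect_amp(function(a) {
    prog_c$amp_contract <- a
    max(occ_series(prog_c, t_peak))
  }, program$occlusion_target)

  # relaxation amplitude: minimum occlusion during the initial relax phase
  t_rel <- (program$f_relax + 0.1) * T
  prog_r <- program
  prog_r$amp_contract <- 0
  cal_r <- bisect_amp(function(a) {
    prog_r$amp_relax <- a
    -min(occ_series(prog_r, t_rel))
  }, -program$relaxation_target)

  out <- program
  out$amp_contract <- cal_c$amp
  out$amp_relax <- cal_r$amp

  # replay with both amplitudes for the achieved values
  full <- occ_series(out, (program$f_relax + program$f_contract + 0.2) * T)
  attr(out, "achieved") <- c(peak_occlusion = max(full),
                             relaxation_occlusion = min(full))
  attr(out, "calibration") <- bind_rows(
    mutate(cal_c$trace, phase = "contraction"),
    mutate(cal_r$trace, phase = "relaxation"))
  out
}
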