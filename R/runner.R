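#' Configuration for one digital-twin run
#'
#' Bundles the geometry, fill, fluid preset and motility choices behind a
#' single object that can be serialised to YAML ([write_config()]) and
#' replayed deterministically: the seed only feeds the optional fluid
#' lattice jitter, which defaults to zero.
#'
#' @param wave_speed Peristaltic wave speed (m s^-1), 0.004 or 0.008.
#' @param preset Fluid preset, `"LOVIS"` or `"HIVIS"`.
#' @param volume Fill volume (m^3), 150e-6 or 200e-6.
#' @param resolution Lattice/smoothing scale factor (1 = full resolution;
#'   2 doubles the particle spacing, an eighth of the particles, with
#'   `alpha` recomputed to preserve the physical viscosity).
#' @param cadence Snapshot/output cadence (s).
#' @param settle_time Damped settling phase before the wave starts (s).
#' @param duration Simulated time after the wave starts (s); default is the
#'   full wave duration.
#' @param through_segment Alternative to `duration`: simulate until this
#'   segment has completed its full cycle (offset + one segment cycle).
#' @param amp_contract,amp_relax Motility amplitudes (N); `NULL` requests
#'   calibration to the occlusion targets.
#' @param jitter Lattice jitter amplitude as a fraction of the spacing.
#' @param seed Seed for the jitter.
#' @param constriction_radius_fraction Passed to [geometry_spec()].
#' @param c0 Artificial speed of sound for the run (m s^-1); the printed
#'   value 0.1 gives Mach ~0.2 at peak backflow.
#' @param gravity Gravity magnitude for the run (m s^-2, acting along -z).
#'   Defaults to 0: the printed lattice-spring constants cannot support the
#'   weight of the pool (the tethers carry mN, the pool weighs ~2 N), so the
#'   digital twin models wall-driven flow without a body force; see the
#'   methods vignette. If enabled, a stiffer c0 is required.
#' @return A `dcm_config` list.
#' @export
run_config <- function(wave_speed = 0.004, preset = "LOVIS", volume = 150e-6,
                       resolution = 2, cadence = 0.25, settle_time = 1.5,
                       duration = NULL, through_segment = NULL,
                       amp_contract = NULL, amp_relax = NULL,
                       jitter = 0, seed = 1L,
                       constriction_radius_fraction = 0.4, c0 = 0.1,
                       gravity = 0) {
  structure(
    list(wave_speed = wave_speed, preset = preset, volume = volume,
         resolution = resolution, cadence = cadence,
         settle_time = settle_time, duration = duration,
         through_segment = through_segment,
         amp_contract = amp_contract, amp_relax = amp_relax,
         jitter = jitter, seed = as.integer(seed),
         constriction_radius_fraction = constriction_radius_fraction,
         c0 = c0, gravity = gravity),
    class = "dcm_config")
}

#' Serialise / parse a run configuration
#'
#' YAML round trip for [run_config()] objects; parsing a serialised
#' configuration reproduces it exactly.
#'
#' @param config A `dcm_config`.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x[!vapply(x, is.null, logical(1))])
}

# session cache for calibrated amplitudes, keyed by wave speed
.amp_cache <- new.env(parent = emptyenv())

calibrated_program <- function(wave_speed, amp_contract = NULL,
                               amp_relax = NULL) {
  program <- motility_program(wave_speed = wave_speed)
  if (!is.null(amp_contract) && !is.null(amp_relax)) {
    program$amp_contract <- amp_contract
    program$amp_relax <- amp_relax
    return(program)
  }
  key <- sprintf("w%.6f", wave_speed)
  if (!is.null(.amp_cache[[key]])) return(.amp_cache[[key]])
  program <- calibrate_occlusion(program)
  .amp_cache[[key]] <- program
  program
}

# axial window of one segment
segment_window <- function(segment, spec = geometry_spec()) {
  seg_len <- spec$dcm_length / 10
  c((segment - 1) * seg_len, segment * seg_len)
}

# slice plane at a segment's centre
segment_plane <- function(segment, spec = geometry_spec()) {
  seg_len <- spec$dcm_length / 10
  (segment - 0.5) * seg_len
}

#' Run the digital twin
#'
#' Builds the domain, calibrates (or reuses) the motility amplitudes, runs
#' the coupled simulation for one full peristaltic wave, and computes the
#' standard analysis series: wall displacement, cross-section velocities at
#' segments 2, 6 and 10, and bottom-wall shear at segments 2 and 6.
#'
#' @param config A [run_config()].
#' @param keep_snapshots Retain raw snapshots on the returned object.
#' @param quiet Suppress progress messages.
#' @return A `dcm_run` list: `config`, `series` (named list of tibbles),
#'   `metrics` (one-row tibble), `diagnostics`, `status`, and optionally
#'   `sim`.
#' @export
dcm_run <- function(config = run_config(), keep_snapshots = FALSE,
                    quiet = TRUE) {
  fp <- fluid_preset(config$preset)
  spec <- geometry_spec(
    constriction_radius_fraction = config$constriction_radius_fraction)
  fill <- if (config$volume > 0) {
    fill_spec(volume = config$volume, preset = config$preset,
              resolution = config$resolution)
  } else NULL   # dry domain
  dx <- (fp$particle_mass / fp$density)^(1 / 3) * config$resolution
  params <- sph_params(resolution = config$resolution,
                       viscosity = fp$viscosity, rho0 = fp$density,
                       c0 = config$c0 %||% 0.1,
                       gravity = c(0, 0, -(config$gravity %||% 0)),
                       lattice_spacing = dx)
  program <- calibrated_program(config$wave_speed, config$amp_contract,
                                config$amp_relax)
  domain <- build_domain(spec, fill)
  particles <- domain$particles
  if (config$jitter > 0) {
    set.seed(config$seed)
    fl <- particles$kind == "fluid"
    nfl <- sum(fl)
    j <- config$jitter * fill$lattice_spacing
    particles$x[fl] <- particles$x[fl] + runif(nfl, -j / 2, j / 2)
    particles$y[fl] <- particles$y[fl] + runif(nfl, -j / 2, j / 2)
    particles$z[fl] <- particles$z[fl] + runif(nfl, -j / 2, j / 2)
  }
  duration <- config$duration %||% (
    if (!is.null(config$through_segment)) {
      program$offsets[config$through_segment] +
        (program$f_relax + program$f_contract + program$f_return) *
          program$segment_period
    } else wave_duration(program))
  if (!quiet)
    message(sprintf("simulating %.0f s (%d particles, dt = %.2g s)",
                    duration, nrow(particles), params$dt))
  sim <- simulate_particles(particles, params, network = domain$network,
                            program = program, duration = duration,
                            dt = params$dt, snapshot_every = config$cadence,
                            settle_time = config$settle_time)
  series <- list(
    wall = wall_displacement_series(sim, spec, segments = c(2, 6, 10)),
    velocity = bind_rows(lapply(c(2, 6, 10), function(s) {
      cs <- cross_section_series(sim, segment_plane(s, spec), spec)
      cs$segment <- s
      cs
    })),
    shear = bind_rows(lapply(c(2, 6), function(s) {
      bottom_wall_shear_series(sim, segment_window(s, spec),
                               viscosity = fp$viscosity, segment = s)
    })))
  safe_max <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  safe_min <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  sh <- series$shear
  metrics <- tibble(
    wave_speed = config$wave_speed, preset = config$preset,
    volume = config$volume, resolution = config$resolution,
    status = sim$status,
    n_fluid = sum(particles$kind == "fluid"),
    peak_mean_shear_seg2 = safe_max(sh$mean_shear[sh$segment == 2]),
    peak_mean_shear_seg6 = safe_max(sh$mean_shear[sh$segment == 6]),
    peak_max_shear = safe_max(sh$max_shear),
    peak_antegrade = safe_max(series$velocity$mean_vx),
    peak_retrograde = safe_min(series$velocity$mean_vx),
    min_fluid_wall = safe_min(
      sim$diagnostics$min_fluid_wall[is.finite(sim$diagnostics$min_fluid_wall)]))
  out <- list(config = config, series = series, metrics = metrics,
              diagnostics = sim$diagnostics, status = sim$status,
              program = program, params = params)
  if (keep_snapshots) out$sim <- sim
  structure(out, class = "dcm_run")
}

#' @export
print.dcm_run <- function(x, ...) {
  cat(sprintf("<dcm_run> %s wave %.1f cm/s, %s, %.0f mL (resolution x%g): %s\n",
              if (x$config$wave_speed <= 0.005) "slow" else "fast",
              100 * x$config$wave_speed, x$config$preset,
              1e6 * x$config$volume, x$config$resolution, x$status))
  print(x$metrics)
  invisible(x)
}

#' Glance at a completed run
#' @param x A `dcm_run`.
#' @param ... Unused.
#' @return Its one-row metrics tibble.
#' @export
glance.dcm_run <- function(x, ...) x$metrics

#' Tidy the analysis series of a run
#' @param x A `dcm_run`.
#' @param series Which series: `"velocity"`, `"shear"` or `"wall"`.
#' @param ... Unused.
#' @export
tidy.dcm_run <- function(x, series = c("velocity", "shear", "wall"), ...) {
  x$series[[match.arg(series)]]
}

#' Full-factorial sweep plan
#'
#' The 2^3 experiment grid: wave speed 0.4/0.8 cm s^-1, LOVIS/HIVIS medium,
#' 150/200 mL fill.
#'
#' @param resolution Lattice scale factor applied to every cell.
#' @param ... Further arguments passed to every [run_config()].
#' @return Tibble of 8 `dcm_config`s in a list-column `config`.
#' @export
sweep_plan <- function(resolution = 2, ...) {
  cells <- expand.grid(wave_speed = c(0.004, 0.008),
                       preset = c("LOVIS", "HIVIS"),
                       volume = c(150e-6, 200e-6),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- as_tibble(cells)
  cells$config <- purrr::pmap(cells, function(wave_speed, preset, volume) {
    run_config(wave_speed = wave_speed, preset = preset, volume = volume,
               resolution = resolution, ...)
  })
  cells
}

#' Run the full factorial sweep
#'
#' Executes all 8 cells of the plan, aggregates the per-cell peak shear and
#' velocity metrics, and computes the main effects of wave speed, viscosity
#' and volume on the peak mean bottom-wall shear at segment 6.
#'
#' @param plan A [sweep_plan()].
#' @param keep_runs Retain the individual `dcm_run` objects.
#' @param quiet Suppress progress messages.
#' @return A `dcm_sweep` list: `results` (8-row tibble), `effects`
#'   (a [main_effects()] table), and optionally `runs`.
#' @export
dcm_sweep <- function(plan = sweep_plan(), keep_runs = FALSE, quiet = TRUE) {
  runs <- vector("list", nrow(plan))
  results <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    cfg <- plan$config[[i]]
    if (!quiet)
      message(sprintf("cell %d/%d: wave %.1f cm/s, %s, %.0f mL", i, nrow(plan),
                      100 * cfg$wave_speed, cfg$preset, 1e6 * cfg$volume))
    run <- tryCatch(dcm_run(cfg, quiet = quiet), error = function(e) e)
    if (inherits(run, "error")) {
      partial <- bind_rows(results[!vapply(results, is.null, logical(1))])
      abort(sprintf("sweep cell %d failed: %s", i, conditionMessage(run)),
            body = c(i = sprintf("%d cells completed before the failure",
                                 nrow(partial))),
            partial = partial)
    }
    runs[[i]] <- run
    results[[i]] <- run$metrics
  }
  results <- bind_rows(results)
  results$viscosity <- results$preset   # factor naming of the experiment grid
  effects <- main_effects(results, response = "peak_mean_shear_seg6")
  out <- list(results = results, effects = effects, plan = plan)
  if (keep_runs) out$runs <- runs
  structure(out, class = "dcm_sweep")
}

#' @export
print.dcm_sweep <- function(x, ...) {
  cat("<dcm_sweep> 8-cell full factorial\n")
  print(x$results)
  cat("\nMain effects on peak mean bottom-wall shear (segment 6):\n")
  print(tidy(x$effects))
  invisible(x)
}

#' @rdname dcm_sweep
#' @param x A `dcm_sweep`.
#' @param ... Unused.
#' @export
tidy.dcm_sweep <- function(x, ...) x$results

#' USPII paddle-apparatus wall shear-rate benchmarks
#'
#' Published tablet-surface shear rates in the USPII dissolution apparatus,
#' approximately constant per paddle speed: 9 s^-1 at 25 rpm, 21.4 s^-1 at
#' 50 rpm, 36 s^-1 at 100 rpm (linear in between).
#'
#' @param rpm Paddle speed (25-100).
#' @return Shear rate (s^-1).
#' @export
uspii_shear_benchmark <- function(rpm = 50) {
  stopifnot(rpm >= 25, rpm <= 100)
  approx(c(25, 50, 100), c(9, 21.4, 36), xout = rpm)$y
}
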