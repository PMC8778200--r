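# Shared cache for expensive simulations so several test files can reuse the
# same run (testthat sources helpers once per session).
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- tryCatch(list(ok = TRUE, value = force(expr)),
                                  error = function(e) list(ok = FALSE, err = e))
  }
  entry <- .sim_cache[[key]]
  if (!entry$ok) stop(entry$err)  # do not recompute a failed heavy step
  entry$value
}

# calibrated slow-wave program (dry membrane bisection; ~1 min)
slow_program_calibrated <- function() {
  cached("slow_program", calibrate_occlusion(motility_program(wave_speed = 0.004)))
}

fast_program_calibrated <- function() {
  cached("fast_program", calibrate_occlusion(motility_program(wave_speed = 0.008)))
}

# settled Poiseuille channel (~1 min)
poiseuille_sim <- function() {
  cached("poiseuille", {
    cs <- make_poiseuille_case()
    list(case = cs,
         sim = simulate_particles(cs$particles, cs$params,
                                  duration = cs$duration, dt = cs$params$dt,
                                  snapshot_every = 0, periodic = cs$periodic,
                                  init_hydrostatic = FALSE))
  })
}

# make dcm_run reuse the test-session calibrations
seed_amp_cache <- function() {
  env <- dcmtwin:::.amp_cache
  if (is.null(env[["w0.004000"]])) env[["w0.004000"]] <- slow_program_calibrated()
  if (is.null(env[["w0.008000"]])) env[["w0.008000"]] <- fast_program_calibrated()
  invisible(env)
}

# reduced-resolution full factorial (the expensive block; ~8 min).
# Cells simulate through the full cycle of segment 6: segment-2 and
# segment-6 statistics are complete by then.
test_sweep <- function() {
  cached("sweep", {
    seed_amp_cache()
    dcm_sweep(sweep_plan(resolution = 3, through_segment = 6),
              keep_runs = TRUE)
  })
}

# particle tibble constructor for hand-built states
particle_tbl <- function(x, y, z, vx = 0, vy = 0, vz = 0, kind = "fluid",
                         mass = 1.324e-5, density = 1017, segment = NA) {
  n <- length(x)
  tibble::tibble(id = seq_len(n), kind = kind, ring = NA_integer_,
                 segment = as.integer(segment),
                 x = x, y = y, z = z,
                 vx = rep_len(vx, n), vy = rep_len(vy, n), vz = rep_len(vz, n),
                 mass = mass, density = density)
}
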