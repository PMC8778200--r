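test_that("configuration round-trips through YAML exactly", {
  cfg <- run_config(wave_speed = 0.008, preset = "HIVIS", volume = 200e-6,
                    resolution = 2.5, amp_contract = 3.1e-4, amp_relax = 1.2e-4)
  f1 <- withr::local_tempfile(fileext = ".yaml")
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, f1)
  back <- read_config(f1)
  write_config(back, f2)
  expect_identical(read_config(f2), back)
  expect_equal(back$wave_speed, cfg$wave_speed)
  expect_equal(back$amp_contract, cfg$amp_contract)
})

test_that("a dry run is deterministic and completes with empty fluid series", {
  cfg <- run_config(volume = 0, duration = 3, settle_time = 0,
                    amp_contract = 3e-4, amp_relax = 1.3e-4)
  r1 <- dcm_run(cfg)
  r2 <- dcm_run(cfg)
  expect_equal(r1$status, "ok")
  expect_identical(r1$series$wall, r2$series$wall)
  expect_identical(r1$series$velocity, r2$series$velocity)
  expect_true(all(is.na(r1$series$velocity$mean_vx)))
  expect_true(all(is.na(r1$series$shear$mean_shear)))
})

test_that("the slow wave reaches segment 10 at the 54 s offset", {
  prog <- slow_program_calibrated()
  expect_equal(prog$offsets[10], 54)
  spec <- geometry_spec()
  dom <- build_domain(spec, fill = NULL)
  params <- sph_params(lattice_spacing = NULL)
  sim <- simulate_particles(dom$particles, params, network = dom$network,
                            program = prog, duration = wave_duration(prog) + 6,
                            dt = 5e-3, snapshot_every = 0.5)
  wd <- wall_displacement_series(sim, spec, segments = c(2, 6, 10))
  s10 <- wd[wd$segment == 10, ]
  # quiet before its offset (small bond crosstalk from segment 9 allowed),
  # strongly active after
  expect_lt(max(abs(s10$occlusion[s10$time < 53])), 10)
  expect_gt(max(abs(s10$occlusion[s10$time > 54])), 50)
  # the stated course at segments 2, 6, 10: minimum near -20%, maximum
  # within 60 +/- 5%, and the return to neutral slower than the contraction
  for (s in c(2, 6, 10)) {
    tr <- wd[wd$segment == s, ]
    expect_lt(min(tr$occlusion), -12)
    expect_gt(min(tr$occlusion), -28)
    expect_gt(max(tr$occlusion), 55)
    expect_lt(max(tr$occlusion), 65)
    t_peak <- tr$time[which.max(tr$occlusion)]
    t_start <- prog$offsets[s]
    rise <- t_peak - t_start
    back <- tr$time[tr$time > t_peak & tr$occlusion < 5][1] - t_peak
    expect_gt(back, rise * 1.2)
  }
})

test_that("USPII benchmark anchors are reproduced", {
  expect_equal(uspii_shear_benchmark(25), 9)
  expect_equal(uspii_shear_benchmark(50), 21.4)
  expect_equal(uspii_shear_benchmark(100), 36)
})

test_that("main effects of identical stub responses are zero", {
  stub <- expand.grid(wave_speed = c(0.004, 0.008),
                      viscosity = c("LOVIS", "HIVIS"),
                      volume = c(150e-6, 200e-6), stringsAsFactors = FALSE)
  stub$peak_mean_shear_seg6 <- 7
  me <- main_effects(stub, response = "peak_mean_shear_seg6")
  expect_equal(me$effect, c(0, 0, 0))
})

test_that("the factorial sweep emits one row per cell and preserves walls", {
  sw <- test_sweep()
  expect_equal(nrow(sw$results), 8)
  expect_true(all(sw$results$status == "ok"))
  expect_s3_class(sw$effects, "main_effects")
  # no fluid particle penetrates the membrane during any full run
  dx <- 2.351e-3 * 3
  expect_true(all(sw$results$min_fluid_wall > 0.2 * dx))
})
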