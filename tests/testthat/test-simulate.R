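test_that("the same seed reproduces a bit-identical stream", {
  cfg <- chamber_config(seed = 5) # noise and drift at defaults
  prof <- emission_profile(450, diurnal_amplitude = 0.2, noise_sd = 0.05)
  a <- simulate_chamber_run(prof, cfg)
  b <- simulate_chamber_run(prof, cfg)
  expect_identical(a$stream, b$stream)
  expect_identical(a$truth$daily, b$truth$daily)
  c <- simulate_chamber_run(prof, cfg, seed = 6)
  expect_false(identical(a$stream$ch4_ppm, c$stream$ch4_ppm))
})

test_that("zero emission leaves the chamber at background", {
  run <- simulate_chamber_run(emission_profile(0), ideal_config())
  expect_true(all(run$stream$ch4_ppm == 2))
  expect_equal(run$truth$daily$g_per_day, 0)
})

test_that("steady-state concentration matches the closed-form mass balance", {
  run <- ideal_run()
  stream <- run$stream
  rc1 <- stream[stream$source == "RC1", ]
  e_lpm <- 454 * 1.3962 / 1440
  env <- add_ventilation_corrections(rc1[1, ])
  expected_diff <- 1e6 * e_lpm / env$dstpvr_lpm
  diff <- rc1$ch4_ppm - 2
  expect_true(all(abs(diff - expected_diff) / expected_diff < 0.001))
})

test_that("the chamber model conserves mass over the run", {
  prof <- emission_profile(454, diurnal_amplitude = 0.3)
  run <- simulate_chamber_run(prof, ideal_config(), truth_resolution_s = 1)
  s <- run$truth$series
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  out_l <- trapz(s$t_min, s$q_dstp_lpm * s$ch4_diff_ppm / 1e6)
  stored_l <- s$v_stp_l[1] *
    (s$ch4_diff_ppm[nrow(s)] - s$ch4_diff_ppm[1]) / 1e6
  in_l <- trapz(s$t_min, s$emission_lpm)
  expect_lt(abs(out_l + stored_l - in_l) / in_l, 1e-6)
})

test_that("door events drive the chamber toward background", {
  cfg <- chamber_config(analyzer_noise_ppm_sd = 0, analyzer_drift_per_day = 0,
                        door_times_of_day = "08:00")
  run <- simulate_chamber_run(emission_profile(454), cfg)
  s <- run$truth$series
  during <- s$ch4_diff_ppm[s$t_min >= 8 * 60 + 25 & s$t_min < 8 * 60 + 30]
  closed <- s$ch4_diff_ppm[s$t_min < 8 * 60]
  expect_lt(max(during), 0.1 * min(closed))
  expect_equal(nrow(run$events), 1)
})

test_that("non-physical configurations are rejected", {
  expect_error(chamber_config(chamber_volume_m3 = -1), "positive")
  expect_error(chamber_config(airflow_m3_h = 0), "positive")
  expect_error(chamber_config(recovery_rate_true = 0.2), "0.5")
  expect_error(chamber_config(temp_c = 60), "45")
  expect_error(simulate_chamber_run(emission_profile(454), ideal_config(), days = 0.2),
               "one day")
  expect_error(emission_profile(-5), "non-negative")
  expect_error(emission_profile(400, diurnal_amplitude = 1.5), "\\[0, 1\\]")
})

test_that("recovery test rises to a plateau scaled by the true recovery", {
  cfg <- ideal_config()
  ts <- simulate_recovery_test(cfg, 2, 120)
  plateau <- ts$measured_lpm[ts$time_min >= 90]
  expect_equal(mean(plateau), 2, tolerance = 1e-3)
  expect_true(ts$measured_lpm[1] < 0.5) # starts near zero

  cfg2 <- chamber_config(recovery_rate_true = 1.046, analyzer_noise_ppm_sd = 0)
  ts2 <- simulate_recovery_test(cfg2, 2, 120)
  expect_equal(mean(ts2$measured_lpm[ts2$time_min >= 90]), 2.092, tolerance = 1e-3)

  expect_warning(short <- simulate_recovery_test(cfg, 2, 20), "time constants")
  expect_true(attr(short, "too_short"))
})

test_that("meal peaks and diurnal cycle shape the true emission rate", {
  prof <- emission_profile(
    400, diurnal_amplitude = 0.1,
    meal_peaks = list(list(time = "08:00", extra = 0.5, duration_min = 60))
  )
  run <- simulate_chamber_run(prof, ideal_config())
  s <- run$truth$series
  peak_rate <- max(s$emission_g_d[s$t_min >= 8 * 60 & s$t_min < 9 * 60])
  expect_gt(peak_rate, 400 * 1.4)
  # daily integral in the ground truth equals the grid mean of the rate
  expect_equal(run$truth$daily$g_per_day, mean(s$emission_g_d), tolerance = 1e-3)
  expect_true(all(s$emission_g_d >= 0))
})
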