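test_that("partial water pressure matches term-by-term polynomial evaluation", {
  # frozen from evaluating the polynomial at 15 C (saturation 17.0524 hPa)
  expect_equal(partial_water_pressure(15, 100), 17.05237, tolerance = 1e-6)
  expect_equal(partial_water_pressure(15, 70), 0.7 * partial_water_pressure(15, 100))
  expect_identical(partial_water_pressure(15, 0), 0)
  expect_error(partial_water_pressure(50, 50), "-5, 45")
  expect_error(partial_water_pressure(15, 120), "0, 100")
})

test_that("volume mixing ratio is the pressure quotient in percent", {
  expect_equal(volume_mixing_ratio(11.937, 1013.25), 100 * 11.937 / 1013.25)
  expect_equal(volume_mixing_ratio(11.937, 1013.25), 1.17809, tolerance = 1e-5)
  expect_identical(volume_mixing_ratio(0, 1013.25), 0)
  expect_equal(volume_mixing_ratio(17.052, 1013.25), 1.68291, tolerance = 1e-5)
  expect_error(volume_mixing_ratio(1020, 1013.25), "exceed")
})

test_that("dry ventilation rate removes the moisture fraction", {
  expect_equal(dry_ventilation_rate(2333.33, 1.178), 2305.843, tolerance = 1e-6)
  expect_equal(dry_ventilation_rate(2333.33, 0), 2333.33)
  expect_equal(dry_ventilation_rate(0, 50), 0)
})

test_that("STP correction scales by temperature and pressure ratios", {
  expect_equal(stp_ventilation_rate(1013.25, 2305.8, 15),
               2305.8 * 273.15 / 288.15, tolerance = 1e-9)
  # 0 C at standard pressure is the identity
  expect_equal(stp_ventilation_rate(1013.25, 1234.5, 0), 1234.5)
  expect_equal(stp_ventilation_rate(900, 2305.8, 15), 1941.467, tolerance = 1e-6)
})

test_that("emission rate divides the concentration flux by the recovery", {
  expect_equal(emission_rate(2185.8, 200, 0.993), 0.4402417, tolerance = 1e-6)
  expect_equal(emission_rate(2185.8, 200, 1), 0.43716, tolerance = 1e-9)
  expect_identical(emission_rate(2185.8, 0, 0.9), 0)
  expect_error(emission_rate(2185.8, 200, 0), "positive")
  # sign follows the concentration difference
  expect_lt(emission_rate(2185.8, -5, 1), 0)
})

test_that("STP ventilation is monotone in temperature and pressure", {
  temps <- seq(-5, 45, by = 2.5)
  out_t <- stp_ventilation_rate(1013.25, 2300, temps)
  expect_true(all(diff(out_t) < 0))
  pressures <- seq(900, 1050, by = 10)
  out_p <- stp_ventilation_rate(pressures, 2300, 16)
  expect_true(all(diff(out_p) > 0))
})

test_that("humidity correction stays in the chamber-setpoint band", {
  # direct evaluation over T in [15,18] C, RH in [60,80] at standard
  # pressure gives DVR/WetVR in [0.98370, 0.98991]
  grid <- expand.grid(temp = seq(15, 18, by = 0.25), rh = seq(60, 80, by = 1))
  ratio <- (100 - volume_mixing_ratio(
    partial_water_pressure(grid$temp, grid$rh), 1013.25
  )) / 100
  expect_true(all(ratio >= 0.98370 & ratio <= 0.98991))
})

test_that("add_ventilation_corrections appends the full chain", {
  d <- tibble::tibble(temp_c = 15, rh_pct = 70, pressure_hpa = 1013.25,
                      wet_vr_lpm = 2333.33)
  out <- add_ventilation_corrections(d)
  expect_equal(out$pwp_hpa, partial_water_pressure(15, 70))
  expect_equal(out$dstpvr_lpm,
               stp_ventilation_rate(1013.25, out$dvr_lpm, 15))
})
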