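t0 <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC")

test_that("two-point fit maps zero to 0 and span to certified", {
  id <- fit_two_point(calibration_record(t0, "CH4", 0, 800, 800))
  expect_equal(id$gain, 1)
  expect_equal(id$offset, 0)

  off <- fit_two_point(calibration_record(t0, "CH4", 2, 800, 802))
  expect_equal(off$gain, 1)
  expect_equal(off$offset, -2)
  expect_equal(predict(off, 2), 0)
  expect_equal(predict(off, 802), 800)

  gn <- fit_two_point(calibration_record(t0, "CH4", 0, 800, 784))
  expect_equal(gn$gain, 800 / 784)

  expect_error(fit_two_point(calibration_record(t0, "CH4", 5, 800, 5)),
               "Degenerate")
})

test_that("calibrating already-corrected readings is the identity", {
  cal <- calibration_record(t0, "CO2", 12, 5000, 5080)
  fit <- fit_two_point(cal)
  recal <- calibration_record(
    t0, "CO2",
    zero_reading = predict(fit, cal$zero_reading),
    span_certified = cal$span_certified,
    span_reading = predict(fit, cal$span_reading)
  )
  refit <- fit_two_point(recal)
  expect_equal(refit$gain, 1, tolerance = 1e-9)
  expect_equal(refit$offset, 0, tolerance = 1e-9)
})

test_that("span gases outside the analyzer ranges are rejected", {
  expect_error(calibration_record(t0, "CH4", 0, 1000, 1000), "800")
  expect_error(calibration_record(t0, "O2", 0, 25, 25), "21")
})

test_that("drift correction interpolates the affine correction in time", {
  stream <- tibble::tibble(
    timestamp = t0 + c(0, 43200, 86400),
    ch4_ppm = c(100, 100, 100)
  )
  cal0 <- calibration_record(t0, "CH4", 0, 800, 800)
  cal1 <- calibration_record(t0 + 86400, "CH4", 0, 800, 800 / 1.02)
  out <- drift_correct(stream, cal0, cal1)
  # start gain 1.00, end gain 1.02 -> exact midpoint gets 1.01
  expect_equal(out$ch4_ppm, c(100, 101, 102))

  same <- drift_correct(stream, cal0, calibration_record(t0 + 86400, "CH4", 0, 800, 800))
  expect_equal(same$ch4_ppm, stream$ch4_ppm)

  expect_warning(flag <- drift_correct(stream, cal0, NULL), "uniformly")
  expect_true(attr(flag, "drift_flagged"))
  expect_error(
    drift_correct(stream, calibration_record(t0 + 10, "CH4", 0, 800, 800), cal1),
    "between"
  )
})

test_that("drift correction preserves order and keeps zeros at zero", {
  stream <- tibble::tibble(
    timestamp = t0 + seq(0, 86400, length.out = 20),
    ch4_ppm = seq(5, 400, length.out = 20)
  )
  cal0 <- calibration_record(t0, "CH4", 0, 800, 790)
  cal1 <- calibration_record(t0 + 86400, "CH4", 0, 800, 812)
  out <- drift_correct(stream, cal0, cal1)
  expect_true(all(diff(out$ch4_ppm) > 0))
  zeros <- tibble::tibble(timestamp = t0 + c(0, 86400), ch4_ppm = c(0, 0))
  expect_equal(drift_correct(zeros, cal0, cal1)$ch4_ppm, c(0, 0))
})

test_that("recovery rate is the plateau mean over the injected rate", {
  # 60 min of rise-free plateau at exactly the stated levels
  flat <- function(level) tibble::tibble(time_min = 0:59, measured_lpm = level)
  expect_equal(recovery_rate(flat(2.0), 2)$recovery_pct, 100)
  expect_equal(recovery_rate(flat(2.092), 2)$recovery_pct, 104.6)
  expect_equal(recovery_rate(flat(1.986), 2)$recovery_pct, 99.3)
  expect_error(recovery_rate(flat(2), 0), "positive")
})

test_that("plateau detection rejects short or unstable series", {
  expect_error(recovery_rate(tibble::tibble(time_min = 0:9, measured_lpm = 2), 2),
               "longer")
  rising <- tibble::tibble(time_min = 0:89, measured_lpm = seq(0, 3, length.out = 90))
  expect_error(recovery_rate(rising, 2), "plateau")
})

test_that("recovery estimate matches the simulator truth", {
  for (r in c(0.993, 1.046)) {
    cfg <- chamber_config(recovery_rate_true = r, analyzer_noise_ppm_sd = 0)
    est <- recovery_rate(simulate_recovery_test(cfg, 2, 120), 2)
    expect_equal(est$recovery_pct, 100 * r, tolerance = 0.002)
  }
  # noisy test: estimate within 3 SE of the truth (fixed seed)
  cfg <- chamber_config(recovery_rate_true = 1, analyzer_noise_ppm_sd = 2)
  ts <- simulate_recovery_test(cfg, 2, 120, seed = 11)
  est <- recovery_rate(ts, 2)
  pl <- est$series[est$series$in_plateau, ]
  se <- sd(pl$measured_lpm) / sqrt(nrow(pl))
  expect_lt(abs(est$plateau_mean_lpm - 2), 3 * se)
})

test_that("tidy and glance expose the calibration and recovery results", {
  fit <- fit_two_point(calibration_record(t0, "CH4", 2, 800, 802))
  td <- tidy(fit)
  expect_equal(td$term, c("gain", "offset"))
  expect_equal(glance(fit)$gain, 1)
  est <- recovery_rate(tibble::tibble(time_min = 0:59, measured_lpm = 2), 2)
  expect_equal(nrow(tidy(est)), 60)
  expect_equal(glance(est)$recovery_pct, 100)
})
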