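#' Analyzer calibration record
#'
#' One two-point calibration of a gas channel: the reading against ultrapure
#' N2 (zero) and the reading against a certified span gas.
#'
#' @param time POSIXct time of the calibration.
#' @param gas `"CH4"`, `"CO2"` or `"O2"`.
#' @param zero_reading Analyzer response at zero gas.
#' @param span_certified Certified span concentration (ppm for CH4/CO2,
#'   percent for O2). Checked against each channel's calibration range
#'   (CH4 0-800 ppm, CO2 0-5000 ppm, O2 0-21%).
#' @param span_reading Analyzer response at the span gas.
#' @return A one-row `calibration_record` tibble.
#' @export
calibration_record <- function(time, gas = "CH4", zero_reading = 0,
                               span_certified = 800, span_reading = 800) {
  gas <- match.arg(gas, c("CH4", "CO2", "O2"))
  rng <- switch(gas, CH4 = 800, CO2 = 5000, O2 = 21)
  if (span_certified <= 0 || span_certified > rng) {
    abort(paste0("`span_certified` for ", gas, " must be in (0, ", rng, "]."))
  }
  structure(
    tibble::tibble(
      time = time, gas = gas,
      zero_reading = zero_reading,
      span_certified = span_certified,
      span_reading = span_reading
    ),
    class = c("calibration_record", "tbl_df", "tbl", "data.frame")
  )
}

#' Fit a two-point affine analyzer correction
#'
#' Solves for the gain and offset that map the zero reading to 0 and the
#' span reading to the certified concentration:
#' `corrected = gain * reading + offset`.
#'
#' @param cal A [calibration_record()].
#' @return A `chamber_cal` object with elements `gain`, `offset`, `gas`,
#'   `time`; supports [tidy()], [glance()] and `predict()`.
#' @examples
#' fit_two_point(calibration_record(Sys.time(), "CH4", 2, 800, 802))
#' @export
fit_two_point <- function(cal) {
  if (isTRUE(all.equal(cal$span_reading, cal$zero_reading))) {
    abort("Degenerate calibration: span and zero readings are equal.")
  }
  gain <- cal$span_certified / (cal$span_reading - cal$zero_reading)
  structure(
    list(
      gain = gain,
      offset = -gain * cal$zero_reading,
      gas = cal$gas,
      time = cal$time
    ),
    class = "chamber_cal"
  )
}

#' @export
print.chamber_cal <- function(x, ...) {
  cat("<chamber_cal> ", x$gas, ": corrected = ",
      format(x$gain), " * reading ", ifelse(x$offset < 0, "- ", "+ "),
      format(abs(x$offset)), "\n", sep = "")
  invisible(x)
}

#' @export
predict.chamber_cal <- function(object, newdata, ...) {
  object$gain * newdata + object$offset
}

#' @rdname fit_two_point
#' @param x A `chamber_cal` object.
#' @param ... Unused.
#' @export
tidy.chamber_cal <- function(x, ...) {
  tibble::tibble(term = c("gain", "offset"), estimate = c(x$gain, x$offset))
}

#' @rdname fit_two_point
#' @export
glance.chamber_cal <- function(x, ...) {
  tibble::tibble(gas = x$gas, gain = x$gain, offset = x$offset, time = x$time)
}

#' Back-correct analyzer drift across a measurement period
#'
#' The analyzer is calibrated at the start and end of each period. Any drift
#' detected at the end is assumed linear in time: the affine correction
#' applied to each reading is interpolated between the start and end
#' two-point fits. With a missing end calibration the start correction is
#' applied uniformly and the result flagged.
#'
#' @param stream Sensor tibble with `timestamp` and the column named by
#'   `value`.
#' @param cal_start,cal_end [calibration_record()]s bracketing the stream in
#'   time; `cal_end` may be `NULL`.
#' @param value Column to correct (default `"ch4_ppm"`).
#' @return The stream with the value column corrected; attribute
#'   `drift_flagged` is `TRUE` when no end calibration was available.
#' @export
drift_correct <- function(stream, cal_start, cal_end = NULL, value = "ch4_ppm") {
  stream <- tibble::as_tibble(stream)
  fit0 <- fit_two_point(cal_start)
  flagged <- is.null(cal_end)
  if (flagged) {
    stream[[value]] <- predict(fit0, stream[[value]])
    attr(stream, "drift_flagged") <- TRUE
    warn("No end-of-period calibration; start calibration applied uniformly.")
    return(stream)
  }
  if (any(stream$timestamp < cal_start$time) || any(stream$timestamp > cal_end$time)) {
    abort("All stream timestamps must lie between the two calibrations.")
  }
  fit1 <- fit_two_point(cal_end)
  span <- as.numeric(difftime(cal_end$time, cal_start$time, units = "secs"))
  w <- if (span <= 0) {
    rep(0, nrow(stream))
  } else {
    as.numeric(difftime(stream$timestamp, cal_start$time, units = "secs")) / span
  }
  gain <- (1 - w) * fit0$gain + w * fit1$gain
  offset <- (1 - w) * fit0$offset + w * fit1$offset
  stream[[value]] <- gain * stream[[value]] + offset
  attr(stream, "drift_flagged") <- FALSE
  stream
}

#' Chamber gas recovery rate from a tracer-injection test
#'
#' Pure CO2 is injected at a known rate until the measured emission reaches a
#' plateau; the recovery rate is the plateau mean as a percentage of the
#' injected rate. The plateau is the longest suffix of the series over which
#' a rolling mean stays within a relative tolerance band.
#'
#' @param test_series Tibble with `time_min` and `measured_lpm` columns
#'   (e.g. from [simulate_recovery_test()]), or a numeric vector of
#'   measured L/min at 1-min spacing.
#' @param injected_lpm Injection rate, L/min.
#' @param window_min Rolling-mean window, minutes.
#' @param tol Relative stability tolerance of the rolling mean.
#' @return A `recovery_test` object with `plateau_mean_lpm`, `recovery_pct`,
#'   the plateau start index, and the series; supports [tidy()], [glance()]
#'   and [ggplot2::autoplot()].
#' @export
recovery_rate <- function(test_series, injected_lpm, window_min = 15, tol = 0.01) {
  if (injected_lpm <= 0) {
    abort("`injected_lpm` must be positive.")
  }
  if (is.numeric(test_series)) {
    test_series <- tibble::tibble(
      time_min = seq_along(test_series) - 1,
      measured_lpm = test_series
    )
  }
  x <- test_series$measured_lpm
  t_min <- test_series$time_min
  n <- length(x)
  step <- if (n > 1) stats::median(diff(t_min)) else 1
  w <- max(2L, ceiling(window_min / step))
  if (n <= w) {
    abort("Series shorter than the plateau-detection window; run a longer test.")
  }
  roll <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 1))
  roll <- roll[!is.na(roll)] # roll[j] summarises raw points j .. j+w-1
  ref <- roll[length(roll)]
  # longest suffix of rolling means staying within +/- tol of the final level
  ok <- abs(roll - ref) <= tol * abs(ref)
  bad <- which(!ok)
  first_ok <- if (length(bad) == 0) 1L else max(bad) + 1L
  if (first_ok > length(roll) - 1L) {
    abort("No plateau found; run a longer recovery test.")
  }
  # start the plateau after the first stable window, so no rise point enters
  plateau_start <- min(first_ok + w - 1L, n)
  idx <- seq(plateau_start, n)
  plateau_mean <- mean(x[idx])
  structure(
    list(
      injected_lpm = injected_lpm,
      plateau_mean_lpm = plateau_mean,
      recovery_pct = 100 * plateau_mean / injected_lpm,
      plateau_start_min = t_min[plateau_start],
      series = tibble::tibble(
        time_min = t_min, measured_lpm = x,
        in_plateau = seq_len(n) >= plateau_start
      )
    ),
    class = "recovery_test"
  )
}

#' @export
print.recovery_test <- function(x, ...) {
  cat("<recovery_test> injected ", format(x$injected_lpm), " L/min, plateau mean ",
      format(x$plateau_mean_lpm), " L/min -> recovery ",
      format(round(x$recovery_pct, 2)), "%\n", sep = "")
  invisible(x)
}

#' @rdname recovery_rate
#' @param x A `recovery_test` object.
#' @param ... Unused.
#' @export
tidy.recovery_test <- function(x, ...) {
  x$series
}

#' @rdname recovery_rate
#' @export
glance.recovery_test <- function(x, ...) {
  tibble::tibble(
    injected_lpm = x$injected_lpm,
    plateau_mean_lpm = x$plateau_mean_lpm,
    recovery_pct = x$recovery_pct,
    plateau_start_min = x$plateau_start_min,
    n_plateau = sum(x$series$in_plateau)
  )
}
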