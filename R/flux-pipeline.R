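#' Compute per-chamber emission series and daily totals from a raw stream
#'
#' The full flux chain: optional analyzer drift back-correction, sampling-
#' cycle demultiplexing with purge discard, wet-to-dry-STP ventilation
#' correction, background (fresh-air) subtraction, recovery correction,
#' event-driven gap filling, and daily summation.
#'
#' Door and failure intervals are gap-filled with the neighbour-mean rule;
#' door events are additionally padded by `pad_after_min` minutes because
#' the chamber needs about three time constants to re-equilibrate after the
#' doors close.
#'
#' @param stream Sensor tibble (see [read_sensor_stream()] for the schema).
#' @param events Event tibble ([event_log()]); `NULL` for none.
#' @param cycle A [sampling_cycle()].
#' @param recovery Named vector of per-chamber recovery fractions, e.g.
#'   `c(RC1 = 0.993, RC2 = 1.046)`; unnamed scalars apply to all chambers.
#' @param cal_start,cal_end Optional [calibration_record()]s for drift
#'   back-correction of the CH4 channel.
#' @param pad_after_min Minutes appended to each door event before gap
#'   filling (re-equilibration).
#' @param fill_k Neighbour points per side for gap filling.
#' @param day_start Origin of 24-h windows; default first retained point.
#' @param coverage_min Minimum measured day fraction for a valid day.
#' @return An `emission_result`: list with `points` (slot-level emission
#'   tibble) and `daily` (per chamber-day totals); supports [tidy()],
#'   [glance()] and [ggplot2::autoplot()].
#' @examples
#' run <- simulate_chamber_run(
#'   emission_profile(454),
#'   chamber_config(analyzer_noise_ppm_sd = 0, analyzer_drift_per_day = 0,
#'                  door_times_of_day = character())
#' )
#' res <- compute_emissions(run$stream, run$events)
#' res$daily
#' @export
compute_emissions <- function(stream, events = NULL, cycle = sampling_cycle(),
                              recovery = 1, cal_start = NULL, cal_end = NULL,
                              pad_after_min = 30, fill_k = 4,
                              day_start = NULL, coverage_min = 0.9) {
  if (!is.null(cal_start)) {
    stream <- drift_correct(stream, cal_start, cal_end, value = "ch4_ppm")
  }

  points <- demultiplex(stream, cycle = cycle) |>
    add_ventilation_corrections()

  rec <- if (is.null(names(recovery)) && length(recovery) == 1) {
    setNames(
      rep(recovery, length(unique(points$chamber))),
      unique(points$chamber)
    )
  } else {
    recovery
  }
  missing_rec <- setdiff(unique(points$chamber), names(rec))
  if (length(missing_rec) > 0) {
    abort(paste0("No recovery rate supplied for chamber(s): ",
                 paste(missing_rec, collapse = ", "), "."))
  }

  points <- points |>
    dplyr::mutate(
      emission_lpm = emission_rate(
        .data$dstpvr_lpm, .data$ch4_diff_ppm,
        unname(rec[.data$chamber])
      )
    )

  fill_events <- events
  if (!is.null(fill_events) && nrow(fill_events) > 0 && pad_after_min > 0) {
    fill_events <- dplyr::mutate(
      fill_events,
      end = .data$end + ifelse(.data$kind == "door", pad_after_min * 60, 0)
    )
  }

  points <- points |>
    dplyr::group_by(.data$chamber) |>
    dplyr::group_modify(~ fill_gaps(.x, fill_events, value = "emission_lpm", k = fill_k)) |>
    dplyr::ungroup()

  daily <- daily_total(
    points,
    cycle_length_min = cycle$cycle_length_min,
    day_start = day_start, coverage_min = coverage_min
  )

  structure(
    list(points = points, daily = daily, cycle = cycle, recovery = rec),
    class = "emission_result"
  )
}

#' @export
print.emission_result <- function(x, ...) {
  cat("<emission_result> ", nrow(x$points), " emission points, ",
      nrow(x$daily), " chamber-day(s)\n", sep = "")
  print(x$daily)
  invisible(x)
}

#' @rdname compute_emissions
#' @param x An `emission_result`.
#' @param type `"daily"` totals or slot-level `"points"`.
#' @param ... Unused.
#' @export
tidy.emission_result <- function(x, type = c("daily", "points"), ...) {
  switch(match.arg(type), daily = x$daily, points = x$points)
}

#' @rdname compute_emissions
#' @export
glance.emission_result <- function(x, ...) {
  x$daily |>
    dplyr::summarise(
      n_days = dplyr::n(),
      mean_g_per_day = mean(.data$total_g_d),
      mean_coverage = mean(.data$coverage),
      n_filled = sum(.data$n_filled),
      n_invalid_days = sum(!.data$valid)
    )
}
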