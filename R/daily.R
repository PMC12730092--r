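#' Daily methane totals from an emission point series
#'
#' Each retained slot value stands for one full sampling cycle in the daily
#' sum, so a point's contribution is `emission_lpm * cycle_length_min`
#' litres. Days are 24-h windows counted from `day_start` (by default the
#' first timestamp, i.e. chamber-entry alignment). Litres convert to grams
#' with 1 g CH4 = 1.3962 L.
#'
#' @param points Tibble with `chamber`, `timestamp`, `emission_lpm` and
#'   (optionally) `filled` columns, e.g. from [compute_emissions()].
#' @param cycle_length_min Minutes represented by each point.
#' @param day_start POSIXct origin of the 24-h windows; default first point.
#' @param coverage_min Minimum measured (unfilled) fraction of the day for a
#'   day to be flagged valid.
#' @return Tibble with one row per chamber-day: `chamber`, `date`,
#'   `total_l_d`, `total_g_d`, `n_points`, `n_filled`, `coverage`, `valid`.
#' @export
daily_total <- function(points, cycle_length_min = 6, day_start = NULL,
                        coverage_min = 0.9) {
  points <- tibble::as_tibble(points)
  if (!"filled" %in% names(points)) {
    points$filled <- FALSE
  }
  if (!"chamber" %in% names(points)) {
    points$chamber <- "RC1"
  }
  day_start <- day_start %||% min(points$timestamp)

  points |>
    dplyr::mutate(
      .day = floor(as.numeric(difftime(.data$timestamp, day_start, units = "days")))
    ) |>
    dplyr::group_by(.data$chamber, .data$.day) |>
    dplyr::summarise(
      total_l_d = sum(.data$emission_lpm) * cycle_length_min,
      n_points = dplyr::n(),
      n_filled = sum(.data$filled),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      date = day_start + .data$.day * 86400,
      total_g_d = .data$total_l_d / L_PER_G_CH4,
      coverage = (.data$n_points - .data$n_filled) * cycle_length_min / 1440,
      valid = .data$coverage >= coverage_min
    ) |>
    dplyr::select(
      "chamber", "date", "total_l_d", "total_g_d",
      "n_points", "n_filled", "coverage", "valid"
    )
}
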