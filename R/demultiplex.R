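#' Sampling cycle description
#'
#' The analyzer is shared between the chamber outlets and the fresh-air inlet
#' by a switching device that pumps each source in turn. The default matches
#' a 6-min cycle of three 2-min slots in the order RC1, RC2, fresh air, with
#' the leading half of each slot discarded while the sample line purges.
#'
#' @param cycle_length_min Full cycle length, minutes.
#' @param slot_length_min Minutes the analyzer spends on each source.
#' @param source_order Character vector of source labels, one per slot.
#' @param purge_fraction Leading fraction of each slot discarded, in \[0, 1).
#' @return An object of class `sampling_cycle`.
#' @examples
#' sampling_cycle()
#' @export
sampling_cycle <- function(cycle_length_min = 6,
                           slot_length_min = 2,
                           source_order = c("RC1", "RC2", "FRESH"),
                           purge_fraction = 0.5) {
  if (!isTRUE(all.equal(slot_length_min * length(source_order), cycle_length_min))) {
    abort("`slot_length_min` times the number of sources must equal `cycle_length_min`.")
  }
  if (purge_fraction < 0 || purge_fraction >= 1) {
    abort("`purge_fraction` must lie in [0, 1).")
  }
  structure(
    list(
      cycle_length_min = cycle_length_min,
      slot_length_min = slot_length_min,
      source_order = source_order,
      purge_fraction = purge_fraction
    ),
    class = "sampling_cycle"
  )
}

#' @export
print.sampling_cycle <- function(x, ...) {
  cat(
    "<sampling_cycle> ", x$cycle_length_min, " min cycle: ",
    paste(x$source_order, collapse = " > "),
    " (", x$slot_length_min, " min each, purge ",
    100 * x$purge_fraction, "%)\n",
    sep = ""
  )
  invisible(x)
}

#' Demultiplex a shared-analyzer sensor stream
#'
#' Splits a multiplexed stream into one retained value per source per slot.
#' Records in the leading `purge_fraction` of a slot are discarded (the
#' sample line still carries the previous source); the remainder of the slot
#' is averaged into a single value stamped at the slot start. The fresh-air
#' CH4 reference is then linearly interpolated onto each chamber's retained
#' timestamps and the chamber-minus-fresh difference computed.
#'
#' @param stream Sensor tibble with columns `timestamp` (POSIXct, strictly
#'   increasing), `source`, `ch4_ppm` and the environment columns `temp_c`,
#'   `rh_pct`, `pressure_hpa`, `wet_vr_lpm`.
#' @param cycle A [sampling_cycle()].
#' @param origin Time at which the first slot starts; defaults to the first
#'   timestamp in the stream.
#' @param fresh_source Label of the fresh-air inlet source.
#' @return Tibble of slot-level chamber readings: `chamber`, `timestamp`
#'   (slot start), `ch4_ppm`, `fresh_ch4_ppm`, `ch4_diff_ppm`, and slot means
#'   of the environment columns.
#' @export
demultiplex <- function(stream, cycle = sampling_cycle(), origin = NULL,
                        fresh_source = "FRESH") {
  stream <- tibble::as_tibble(stream)
  if (is.unsorted(stream$timestamp, strictly = TRUE)) {
    abort("Stream timestamps must be strictly increasing.")
  }
  unknown <- setdiff(unique(stream$source), cycle$source_order)
  if (length(unknown) > 0) {
    abort(paste0(
      "Unknown source label(s): ", paste(unknown, collapse = ", "),
      "; expected one of ", paste(cycle$source_order, collapse = ", "), "."
    ))
  }
  origin <- origin %||% stream$timestamp[[1]]

  t_min <- as.numeric(difftime(stream$timestamp, origin, units = "mins"))
  slot_idx <- floor(t_min / cycle$slot_length_min)
  phase <- t_min / cycle$slot_length_min - slot_idx

  env_cols <- intersect(
    c("temp_c", "rh_pct", "pressure_hpa", "wet_vr_lpm", "co2_ppm", "o2_pct"),
    names(stream)
  )
  slotted <- stream |>
    dplyr::mutate(.slot = slot_idx, .phase = phase) |>
    dplyr::filter(.data$.phase >= cycle$purge_fraction) |>
    dplyr::group_by(.data$source, .data$.slot) |>
    dplyr::summarise(
      ch4_ppm = mean(.data$ch4_ppm),
      dplyr::across(dplyr::all_of(env_cols), mean),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      timestamp = origin + .data$.slot * cycle$slot_length_min * 60
    ) |>
    dplyr::arrange(.data$timestamp)

  fresh <- dplyr::filter(slotted, .data$source == fresh_source)
  chambers <- dplyr::filter(slotted, .data$source != fresh_source)
  if (nrow(fresh) == 0) {
    abort("No fresh-air readings found in the stream.")
  }

  ref <- if (nrow(fresh) == 1) {
    rep(fresh$ch4_ppm, nrow(chambers))
  } else {
    approx(
      x = as.numeric(fresh$timestamp), y = fresh$ch4_ppm,
      xout = as.numeric(chambers$timestamp), rule = 2
    )$y
  }

  chambers |>
    dplyr::mutate(
      fresh_ch4_ppm = ref,
      ch4_diff_ppm = .data$ch4_ppm - .data$fresh_ch4_ppm
    ) |>
    dplyr::rename(chamber = "source") |>
    dplyr::select(-".slot") |>
    dplyr::relocate("chamber", "timestamp")
}
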