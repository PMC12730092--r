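#' Plot an emission series
#'
#' Slot-level emission rates over time, faceted by chamber, with gap-filled
#' points highlighted.
#'
#' @param object An `emission_result` from [compute_emissions()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.emission_result <- function(object, ...) {
  ggplot2::ggplot(
    object$points,
    ggplot2::aes(x = .data$timestamp, y = .data$emission_lpm)
  ) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(
      ggplot2::aes(colour = .data$filled), size = 0.6
    ) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "black", `TRUE` = "orange"),
      labels = c(`FALSE` = "measured", `TRUE` = "gap-filled"),
      name = NULL
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chamber), ncol = 1) +
    ggplot2::labs(x = NULL, y = expression(CH[4] ~ "(L/min)")) +
    ggplot2::theme_minimal()
}

#' Plot a recovery test
#'
#' Measured emission over time with the detected plateau shaded and the
#' plateau mean drawn.
#'
#' @param object A `recovery_test` from [recovery_rate()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.recovery_test <- function(object, ...) {
  ggplot2::ggplot(
    object$series,
    ggplot2::aes(x = .data$time_min, y = .data$measured_lpm)
  ) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$in_plateau)) +
    ggplot2::geom_hline(yintercept = object$plateau_mean_lpm, linetype = 2) +
    ggplot2::geom_hline(yintercept = object$injected_lpm, linetype = 3) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "steelblue"),
      labels = c(`FALSE` = "rise", `TRUE` = "plateau"), name = NULL
    ) +
    ggplot2::labs(
      x = "time (min)", y = "measured (L/min)",
      subtitle = paste0("recovery ", round(object$recovery_pct, 1), "%")
    ) +
    ggplot2::theme_minimal()
}

#' Energy partition bar chart
#'
#' Stacked per-cow partition of gross energy intake into fecal, urinary,
#' methane and milk energy plus the remainder.
#'
#' @param balance_tbl Output of [nutrient_balance()].
#' @return A ggplot.
#' @export
plot_energy_partition <- function(balance_tbl) {
  id <- if ("cow_id" %in% names(balance_tbl)) "cow_id" else NULL
  d <- balance_tbl |>
    dplyr::mutate(
      .id = if (is.null(id)) as.character(dplyr::row_number()) else .data$cow_id,
      remainder = .data$energy_gei - .data$energy_e_feces -
        .data$energy_e_urine - .data$energy_e_methane - .data$energy_e_milk
    ) |>
    dplyr::select(
      ".id",
      feces = "energy_e_feces", urine = "energy_e_urine",
      methane = "energy_e_methane", milk = "energy_e_milk",
      remainder = "remainder"
    ) |>
    tidyr::pivot_longer(-".id", names_to = "component", values_to = "mj_d")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$.id, y = .data$mj_d,
                                  fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "MJ/d", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Nitrogen partition bar chart
#'
#' Stacked per-cow partition of intake N into fecal, urinary, milk and
#' retained-minus-milk nitrogen.
#'
#' @param balance_tbl Output of [nutrient_balance()].
#' @return A ggplot.
#' @export
plot_nitrogen_partition <- function(balance_tbl) {
  d <- balance_tbl |>
    dplyr::mutate(
      .id = if ("cow_id" %in% names(balance_tbl)) {
        .data$cow_id
      } else {
        as.character(dplyr::row_number())
      },
      body = .data$retained_n - .data$milk_n
    ) |>
    dplyr::select(
      ".id",
      fecal = "fecal_n", urinary = "urinary_n",
      milk = "milk_n", body = "body"
    ) |>
    tidyr::pivot_longer(-".id", names_to = "component", values_to = "g_d")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$.id, y = .data$g_d,
                                  fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "N (g/d)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
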