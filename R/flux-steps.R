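#' Partial water pressure of chamber air
#'
#' Saturation vapour pressure from a sixth-order polynomial in temperature,
#' scaled by relative humidity. This is the first step in converting the wet
#' ventilation rate measured by the chamber flow meters to a dry flow.
#'
#' @param temp_c Chamber temperature, degrees C. Must lie in \[-5, 45\], the
#'   validity range of the polynomial around dairy-chamber setpoints.
#' @param rh_pct Relative humidity, percent, in \[0, 100\].
#' @return Partial water pressure, hPa.
#' @examples
#' partial_water_pressure(15, 70)
#' @export
partial_water_pressure <- function(temp_c, rh_pct) {
  if (any(rh_pct < 0 | rh_pct > 100, na.rm = TRUE)) {
    abort("`rh_pct` must be within [0, 100].")
  }
  if (any(temp_c < -5 | temp_c > 45, na.rm = TRUE)) {
    abort("`temp_c` outside the polynomial validity range [-5, 45] degrees C.")
  }
  sat <- 6.1117675 +
    0.4439 * temp_c +
    0.014305 * temp_c^2 +
    0.000265 * temp_c^3 +
    0.00000302 * temp_c^4 +
    0.0000000204 * temp_c^5 +
    0.00000000006388 * temp_c^6
  sat * rh_pct / 100
}

#' Volume mixing ratio of water vapour
#'
#' @param pwp_hpa Partial water pressure, hPa (see [partial_water_pressure()]).
#' @param pressure_hpa Total air pressure, hPa; must exceed `pwp_hpa`.
#' @return Moisture volume mixing ratio, percent.
#' @examples
#' volume_mixing_ratio(11.937, 1013.25)
#' @export
volume_mixing_ratio <- function(pwp_hpa, pressure_hpa) {
  if (any(pwp_hpa < 0, na.rm = TRUE)) {
    abort("`pwp_hpa` must be non-negative.")
  }
  if (any(pressure_hpa <= pwp_hpa, na.rm = TRUE)) {
    abort("Air pressure must exceed the partial water pressure.")
  }
  100 * pwp_hpa / pressure_hpa
}

#' Dry ventilation rate
#'
#' Removes the water-vapour fraction from the wet ventilation rate recorded
#' by the flow meters.
#'
#' @param wet_vr_lpm Wet ventilation rate, L/min.
#' @param vmr_pct Moisture volume mixing ratio, percent
#'   (see [volume_mixing_ratio()]).
#' @return Dry ventilation rate, L/min.
#' @examples
#' dry_ventilation_rate(2333.33, 1.178)
#' @export
dry_ventilation_rate <- function(wet_vr_lpm, vmr_pct) {
  if (any(wet_vr_lpm < 0, na.rm = TRUE)) {
    abort("`wet_vr_lpm` must be non-negative.")
  }
  wet_vr_lpm * (100 - vmr_pct) / 100
}

#' Dry ventilation rate at standard temperature and pressure
#'
#' Converts the dry ventilation rate at chamber conditions to 0 degrees C and
#' 1013.25 hPa, so that a fixed volumetric-to-mass conversion applies.
#'
#' @param pressure_hpa Air pressure, hPa.
#' @param dvr_lpm Dry ventilation rate at chamber conditions, L/min.
#' @param temp_c Chamber temperature, degrees C.
#' @return Dry STP ventilation rate, L/min.
#' @examples
#' stp_ventilation_rate(1013.25, 2305.8, 15)
#' @export
stp_ventilation_rate <- function(pressure_hpa, dvr_lpm, temp_c) {
  if (any(temp_c <= -T_ZERO_K, na.rm = TRUE)) {
    abort("`temp_c` must be above absolute zero.")
  }
  (pressure_hpa * dvr_lpm) / (temp_c + T_ZERO_K) * T_ZERO_K / P_STD_HPA
}

#' Instantaneous methane emission rate
#'
#' Emission in L/min from the background-corrected concentration difference,
#' the dry STP ventilation rate, and the chamber gas recovery rate.
#'
#' @param dstpvr_lpm Dry STP ventilation rate, L/min
#'   (see [stp_ventilation_rate()]).
#' @param ch4_diff_ppm Chamber minus fresh-air CH4 concentration, ppm.
#' @param recovery_rate Chamber gas recovery as a fraction (1 = perfect);
#'   measured emissions are divided by it.
#' @return Emission rate, L/min.
#' @examples
#' emission_rate(2185.8, 200, 0.993)
#' @export
emission_rate <- function(dstpvr_lpm, ch4_diff_ppm, recovery_rate = 1) {
  if (any(recovery_rate <= 0, na.rm = TRUE)) {
    abort("`recovery_rate` must be positive.")
  }
  (dstpvr_lpm * ch4_diff_ppm / 1e6) / recovery_rate
}

#' Add ventilation-correction columns to a sensor table
#'
#' Applies the full wet-to-dry-STP correction chain to each row of a sensor
#' table, adding `pwp_hpa`, `vmr_pct`, `dvr_lpm` and `dstpvr_lpm` columns.
#'
#' @param data Data frame with `temp_c`, `rh_pct`, `pressure_hpa` and
#'   `wet_vr_lpm` columns.
#' @return The input as a tibble with the four correction columns appended.
#' @export
add_ventilation_corrections <- function(data) {
  data <- tibble::as_tibble(data)
  dplyr::mutate(
    data,
    pwp_hpa = partial_water_pressure(.data$temp_c, .data$rh_pct),
    vmr_pct = volume_mixing_ratio(.data$pwp_hpa, .data$pressure_hpa),
    dvr_lpm = dry_ventilation_rate(.data$wet_vr_lpm, .data$vmr_pct),
    dstpvr_lpm = stp_ventilation_rate(.data$pressure_hpa, .data$dvr_lpm, .data$temp_c)
  )
}
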