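# Shared fixtures: one ideal (noise-free, drift-free, doors-closed) chamber
# run at a constant 454 g/d used across test files, plus small builders.

ideal_config <- function(...) {
  chamber_config(
    temp_c = 16, rh_pct = 70, recovery_rate_true = 1,
    analyzer_noise_ppm_sd = 0, analyzer_drift_per_day = 0,
    door_times_of_day = character(),
    ...
  )
}

ideal_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_chamber_run(emission_profile(454), ideal_config())
    }
    cache
  }
})

# multiplexed stream with constant per-source concentrations, 30-s cadence
constant_stream <- function(minutes, values = c(RC1 = 210, RC2 = 150, FRESH = 2),
                            start = as.POSIXct("2024-03-01 00:00:00", tz = "UTC"),
                            cycle = sampling_cycle()) {
  t_min <- seq(0, minutes - 0.5, by = 0.5)
  slot <- floor(t_min / cycle$slot_length_min) %% length(cycle$source_order)
  source <- cycle$source_order[slot + 1]
  tibble::tibble(
    timestamp = start + t_min * 60,
    source = source,
    ch4_ppm = unname(values[source]),
    co2_ppm = 500, o2_pct = 20.9,
    temp_c = 16, rh_pct = 70, pressure_hpa = 1013.25,
    wet_vr_lpm = 140 * 1000 / 60
  )
}

# minute-spaced scalar series for gap-filling tests
value_series <- function(values, start = as.POSIXct("2024-03-01 00:00:00", tz = "UTC")) {
  tibble::tibble(
    timestamp = start + (seq_along(values) - 1) * 60,
    emission_lpm = values
  )
}
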