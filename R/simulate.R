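#' True enteric emission profile
#'
#' Ground-truth instantaneous methane emission of the animal, used by the
#' chamber simulator: a baseline with an optional diurnal sinusoid, raised-
#' cosine meal peaks, and multiplicative process noise.
#'
#' @param baseline_g_d Baseline emission, g/day.
#' @param diurnal_amplitude Sinusoid amplitude as a fraction of baseline,
#'   in \[0, 1\] (minimum at 06:00, maximum at 18:00).
#' @param meal_peaks List of `list(time = "HH:MM", extra = fraction,
#'   duration_min = minutes)` bumps added to the baseline.
#' @param noise_sd Multiplicative process-noise SD as a fraction of the
#'   instantaneous rate, redrawn each minute.
#' @return An `emission_profile` object.
#' @examples
#' emission_profile(454)
#' @export
emission_profile <- function(baseline_g_d, diurnal_amplitude = 0,
                             meal_peaks = list(), noise_sd = 0) {
  if (baseline_g_d < 0) abort("`baseline_g_d` must be non-negative.")
  if (diurnal_amplitude < 0 || diurnal_amplitude > 1) {
    abort("`diurnal_amplitude` must lie in [0, 1].")
  }
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  structure(
    list(
      baseline_g_d = baseline_g_d,
      diurnal_amplitude = diurnal_amplitude,
      meal_peaks = meal_peaks,
      noise_sd = noise_sd
    ),
    class = "emission_profile"
  )
}

hhmm_to_min <- function(x) {
  if (is.numeric(x)) return(x)
  hm <- as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
  hm[1] * 60 + hm[2]
}

# deterministic part of the emission rate (g/d) at minutes-of-day `tod`
profile_rate_g_d <- function(profile, tod) {
  r <- profile$baseline_g_d *
    (1 + profile$diurnal_amplitude * sin(2 * pi * (tod - 360) / 1440))
  for (pk in profile$meal_peaks) {
    start <- hhmm_to_min(pk$time)
    x <- (tod - start) %% 1440
    inside <- x < pk$duration_min
    bump <- ifelse(
      inside,
      pk$extra * 0.5 * (1 - cos(2 * pi * x / pk$duration_min)),
      0
    )
    r <- r + profile$baseline_g_d * bump
  }
  pmax(r, 0)
}

#' Respiration-chamber simulation configuration
#'
#' Physical and instrumental parameters of one open-circuit chamber. The
#' defaults reproduce the study setup: a 23 m3 chamber ventilated at
#' 140 m3/h (about six air changes per hour), held at 16 degrees C, 70%
#' relative humidity and ambient pressure, sampled on a 6-min three-source
#' cycle, with doors opened for 30 min twice a day.
#'
#' @param chamber_volume_m3 Chamber volume, m3.
#' @param airflow_m3_h Wet ventilation rate, m3/h.
#' @param temp_c,rh_pct,pressure_hpa Chamber environment; each may be a
#'   scalar or a function of minutes since run start.
#' @param recovery_rate_true True chamber gas recovery as a fraction,
#'   in (0.5, 1.5).
#' @param analyzer_noise_ppm_sd Additive analyzer noise SD, ppm.
#' @param analyzer_drift_per_day Fractional analyzer gain change per day
#'   (linear in time).
#' @param background_ch4_ppm Fresh-air CH4 concentration, ppm.
#' @param cycle A [sampling_cycle()].
#' @param door_times_of_day `"HH:MM"` door-opening times; `character()`
#'   disables door events.
#' @param door_duration_min Minutes each opening lasts.
#' @param door_vent_factor Multiplier on the ventilation rate while a door
#'   is open (open doors flush the chamber toward background).
#' @param record_interval_s Analyzer logging interval, seconds.
#' @param seed Default RNG seed for simulations using this configuration.
#' @return A `chamber_config` object.
#' @export
chamber_config <- function(chamber_volume_m3 = 23,
                           airflow_m3_h = 140,
                           temp_c = 16,
                           rh_pct = 70,
                           pressure_hpa = 1013.25,
                           recovery_rate_true = 1,
                           analyzer_noise_ppm_sd = 0.5,
                           analyzer_drift_per_day = 0.005,
                           background_ch4_ppm = 2,
                           cycle = sampling_cycle(),
                           door_times_of_day = c("07:00", "16:00"),
                           door_duration_min = 30,
                           door_vent_factor = 20,
                           record_interval_s = 30,
                           seed = 1L) {
  if (chamber_volume_m3 <= 0) abort("`chamber_volume_m3` must be positive.")
  if (airflow_m3_h <= 0) abort("`airflow_m3_h` must be positive.")
  if (recovery_rate_true <= 0.5 || recovery_rate_true >= 1.5) {
    abort("`recovery_rate_true` must lie in (0.5, 1.5).")
  }
  chk_env <- function(x, lo, hi, name) {
    if (is.numeric(x) && any(x < lo | x > hi)) {
      abort(paste0("`", name, "` must lie in [", lo, ", ", hi, "]."))
    }
  }
  chk_env(temp_c, -5, 45, "temp_c")
  chk_env(rh_pct, 0, 100, "rh_pct")
  structure(
    list(
      chamber_volume_m3 = chamber_volume_m3,
      airflow_m3_h = airflow_m3_h,
      wet_vr_lpm = airflow_m3_h * 1000 / 60,
      temp_c = temp_c, rh_pct = rh_pct, pressure_hpa = pressure_hpa,
      recovery_rate_true = recovery_rate_true,
      analyzer_noise_ppm_sd = analyzer_noise_ppm_sd,
      analyzer_drift_per_day = analyzer_drift_per_day,
      background_ch4_ppm = background_ch4_ppm,
      cycle = cycle,
      door_times_of_day = door_times_of_day,
      door_duration_min = door_duration_min,
      door_vent_factor = door_vent_factor,
      record_interval_s = record_interval_s,
      seed = seed
    ),
    class = "chamber_config"
  )
}

env_at <- function(x, t_min) {
  if (is.function(x)) x(t_min) else rep(x, length(t_min))
}

# evaluate RNG-dependent code under `seed` without touching the caller's RNG
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Integrate the well-mixed chamber model on a fine grid.
# e_lpm: emission L(STP)/min; q_lpm: dry STP ventilation; v_l: dry STP gas
# volume of the chamber. Returns concentration above background, ppm.
integrate_chamber <- function(e_lpm, q_lpm, v_l, dt_min, c0_ppm) {
  n <- length(e_lpm)
  css <- 1e6 * e_lpm / q_lpm
  a <- exp(-q_lpm * dt_min / v_l)
  conc <- numeric(n + 1)
  conc[1] <- c0_ppm
  for (i in seq_len(n)) {
    conc[i + 1] <- css[i] + (conc[i] - css[i]) * a[i]
  }
  conc
}

#' Simulate a respiration-chamber run
#'
#' Generates a multiplexed analyzer stream, an event log and ground truth
#' for one chamber over `days` days. The chamber is a single well-mixed
#' compartment: `dC/dt = (E(t) - Q (C - C_bg)) / V`, integrated exactly over
#' 1-s steps (piecewise-constant coefficients) and started at the
#' quasi-steady state, as chambers are run for many hours before an animal
#' enters. Door openings multiply the exchange rate so the concentration
#' collapses toward background. The analyzer sees the active source of the
#' sampling cycle, scaled by the true recovery and a linear gain drift, plus
#' additive Gaussian noise.
#'
#' @param profile An [emission_profile()].
#' @param config A [chamber_config()].
#' @param days Simulation horizon in whole days (>= 1).
#' @param start POSIXct start of the run.
#' @param chamber Source label for this chamber (`"RC1"` or `"RC2"`).
#' @param seed RNG seed; defaults to `config$seed`.
#' @param truth_resolution_s Grid spacing of the ground-truth series.
#' @return A list with elements `stream` (sensor tibble), `events` (event
#'   tibble), and `truth` (list: `daily` tibble of exact daily emissions,
#'   `series` fine-grid tibble of true state, and the inputs used).
#' @export
simulate_chamber_run <- function(profile, config = chamber_config(), days = 1,
                                 start = as.POSIXct("2024-03-01 00:00:00", tz = "UTC"),
                                 chamber = "RC1", seed = NULL,
                                 truth_resolution_s = 60) {
  stopifnot(inherits(profile, "emission_profile"), inherits(config, "chamber_config"))
  if (days < 1) abort("Simulation horizon must be at least one day.")
  seed <- seed %||% config$seed

  dt_s <- 1
  dt_min <- dt_s / 60
  n <- as.integer(days * 86400 / dt_s)
  t_min <- (seq_len(n) - 1) * dt_min # interval-start labels
  tod <- t_min %% 1440

  events <- if (length(config$door_times_of_day) > 0) {
    door_schedule(start, start + days * 86400,
                  times_of_day = config$door_times_of_day,
                  duration_min = config$door_duration_min)
  } else {
    event_log()
  }

  with_seed(seed, {
    # true emission, g/d on the fine grid; process noise redrawn per minute
    rate_g_d <- profile_rate_g_d(profile, tod)
    if (profile$noise_sd > 0) {
      minute_idx <- floor(t_min) + 1
      mult <- pmax(1 + rnorm(ceiling(days * 1440), sd = profile$noise_sd), 0)
      rate_g_d <- rate_g_d * mult[minute_idx]
    }
    e_lpm <- rate_g_d * L_PER_G_CH4 / 1440

    temp <- env_at(config$temp_c, t_min)
    rh <- env_at(config$rh_pct, t_min)
    press <- env_at(config$pressure_hpa, t_min)
    pwp <- partial_water_pressure(temp, rh)
    q_dstp <- stp_ventilation_rate(
      press,
      dry_ventilation_rate(config$wet_vr_lpm, volume_mixing_ratio(pwp, press)),
      temp
    )
    door_open <- in_any_interval(start + t_min * 60, events)
    q_eff <- q_dstp * ifelse(door_open, config$door_vent_factor, 1)
    v_stp <- config$chamber_volume_m3 * 1000 *
      (T_ZERO_K / (temp + T_ZERO_K)) * ((press - pwp) / P_STD_HPA)

    conc_path <- integrate_chamber(e_lpm, q_eff, v_stp, dt_min,
                                   c0_ppm = 1e6 * e_lpm[1] / q_eff[1])
    conc <- conc_path[seq_len(n)]

    # analyzer records
    rec_idx <- seq(1, n, by = config$record_interval_s / dt_s)
    rec_t_min <- t_min[rec_idx]
    slot <- floor(rec_t_min / config$cycle$slot_length_min) %%
      length(config$cycle$source_order)
    source <- config$cycle$source_order[slot + 1]
    true_ppm <- ifelse(
      source == chamber,
      config$background_ch4_ppm + config$recovery_rate_true * conc[rec_idx],
      config$background_ch4_ppm
    )
    gain <- 1 + config$analyzer_drift_per_day * rec_t_min / 1440
    noise <- if (config$analyzer_noise_ppm_sd > 0) {
      rnorm(length(rec_idx), sd = config$analyzer_noise_ppm_sd)
    } else {
      0
    }
    stream <- tibble::tibble(
      timestamp = start + rec_t_min * 60,
      source = source,
      ch4_ppm = gain * true_ppm + noise,
      co2_ppm = ifelse(source == chamber, 1500, 420),
      o2_pct = ifelse(source == chamber, 20.5, 20.95),
      temp_c = temp[rec_idx],
      rh_pct = rh[rec_idx],
      pressure_hpa = press[rec_idx],
      wet_vr_lpm = config$wet_vr_lpm
    )

    day_idx <- floor(t_min / 1440)
    daily <- tibble::tibble(
      chamber = chamber,
      date = start + sort(unique(day_idx)) * 86400,
      g_per_day = as.numeric(tapply(rate_g_d, day_idx, mean))
    )

    truth_idx <- seq(1, n, by = truth_resolution_s / dt_s)
    series <- tibble::tibble(
      timestamp = start + t_min[truth_idx] * 60,
      t_min = t_min[truth_idx],
      emission_g_d = rate_g_d[truth_idx],
      emission_lpm = e_lpm[truth_idx],
      ch4_diff_ppm = conc[truth_idx],
      q_dstp_lpm = q_eff[truth_idx],
      v_stp_l = v_stp[truth_idx]
    )

    list(
      stream = stream,
      events = events,
      truth = list(
        daily = daily, series = series,
        profile = profile, config = config, seed = seed, chamber = chamber
      )
    )
  })
}

#' Simulate a CO2 recovery test
#'
#' Pure CO2 is injected into an empty chamber at a constant rate; the
#' measured emission series rises to a plateau whose mean, relative to the
#' injected rate, is the chamber recovery. The returned series carries the
#' attribute `too_short = TRUE` when the duration is under three chamber
#' time constants, i.e. before a plateau can exist.
#'
#' @param config A [chamber_config()]; `recovery_rate_true` scales the
#'   measured series.
#' @param injected_lpm Injection rate, L/min (the study rotameter setting
#'   was 2 L/min).
#' @param duration_min Test length, minutes.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return Tibble with `time_min`, `co2_diff_ppm` and `measured_lpm`.
#' @export
simulate_recovery_test <- function(config = chamber_config(), injected_lpm = 2,
                                   duration_min = 120, seed = NULL) {
  stopifnot(inherits(config, "chamber_config"))
  if (injected_lpm <= 0) abort("`injected_lpm` must be positive.")
  seed <- seed %||% config$seed

  dt_min <- 1 / 60
  n <- as.integer(duration_min / dt_min)
  t_min <- (seq_len(n) - 1) * dt_min
  temp <- env_at(config$temp_c, t_min)
  rh <- env_at(config$rh_pct, t_min)
  press <- env_at(config$pressure_hpa, t_min)
  pwp <- partial_water_pressure(temp, rh)
  q_dstp <- stp_ventilation_rate(
    press,
    dry_ventilation_rate(config$wet_vr_lpm, volume_mixing_ratio(pwp, press)),
    temp
  )
  v_stp <- config$chamber_volume_m3 * 1000 *
    (T_ZERO_K / (temp + T_ZERO_K)) * ((press - pwp) / P_STD_HPA)
  tau_min <- mean(v_stp / q_dstp)

  conc_path <- integrate_chamber(rep(injected_lpm, n), q_dstp, v_stp, dt_min, 0)
  # one reading per minute on the dedicated test record
  idx <- seq(1, n, by = 60)
  conc <- config$recovery_rate_true * conc_path[idx]
  conc_obs <- with_seed(seed, {
    if (config$analyzer_noise_ppm_sd > 0) {
      conc + rnorm(length(idx), sd = config$analyzer_noise_ppm_sd)
    } else {
      conc
    }
  })
  out <- tibble::tibble(
    time_min = t_min[idx],
    co2_diff_ppm = conc_obs,
    measured_lpm = q_dstp[idx] * conc_obs / 1e6
  )
  if (duration_min < 3 * tau_min) {
    attr(out, "too_short") <- TRUE
    warn("Test shorter than three chamber time constants; no plateau expected.")
  } else {
    attr(out, "too_short") <- FALSE
  }
  out
}
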