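#' Default parameter ranges for synthetic animal records
#'
#' Cow-level distributions emulating the study herd: multiparous Holsteins
#' around 555-590 kg eating 26-28 kg DM/d of a 20.4% CP total mixed ration
#' (16.42 MJ GE/kg DM), producing about 40 kg milk/d at 3.4% fat and 3.3%
#' protein, with DM digestibility near 68% and methane yield near 16.8 g/kg
#' DMI. Means and SDs can be overridden individually.
#'
#' @param ... Named overrides of the default entries.
#' @return Named list of parameter entries (`c(mean, sd)` pairs, ranges, or
#'   scalars).
#' @export
animal_parameters <- function(...) {
  defaults <- list(
    dmi_range_kg_d = c(26, 28),
    cp_frac = 0.204,
    ndf_frac = 0.3048,
    ndfi_frac = 0.0895,
    ge_mj_kg = 16.42,
    dmd_pct = c(mean = 67.7, sd = 1.5),
    ged_pct = c(mean = 62.8, sd = 1.5),
    ndfd_pct = c(mean = 35.5, sd = 3),
    milk_kg_d = c(mean = 39.8, sd = 3),
    fat_pct = c(mean = 3.41, sd = 0.2),
    protein_pct = c(mean = 3.34, sd = 0.2),
    lactose_pct = c(mean = 5.09, sd = 0.15),
    ch4_yield_g_kg = c(mean = 16.8, sd = 1),
    fecal_n_frac_intake = c(mean = 0.244, sd = 0.02),
    urinary_n_frac_intake = c(mean = 0.394, sd = 0.03),
    urine_creatinine_mg_l = c(mean = 700, sd = 80),
    bw_kg = c(mean = 586, sd = 30),
    bcs = c(mean = 3.2, sd = 0.1),
    day_cv = 0.02
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("Unknown parameter(s): ", paste(unknown, collapse = ", "), "."))
  }
  utils::modifyList(defaults, overrides)
}

# draw n positive values from N(mean, sd); negatives are resampled
rnorm_pos <- function(n, par, log_fn = NULL) {
  x <- rnorm(n, par[["mean"]], par[["sd"]])
  bad <- which(x <= 0)
  tries <- 0
  while (length(bad) > 0 && tries < 100) {
    x[bad] <- rnorm(length(bad), par[["mean"]], par[["sd"]])
    bad <- which(x <= 0)
    tries <- tries + 1
  }
  if (length(bad) > 0) abort("Could not draw positive values; check parameters.")
  if (tries > 0 && !is.null(log_fn)) log_fn(tries)
  x
}

#' Simulate per-cow daily nutrition records with known ground truth
#'
#' Generates internally consistent per-cow per-day intake, milk, fecal,
#' urine and body records plus methane production, then derives the true
#' balance tables by applying the package's balance chain to the noise-free
#' records. Observed records are the truth with multiplicative Gaussian
#' measurement noise on every assayed quantity; with `noise = 0` the
#' observed records equal the truth and [nutrient_balance()] reproduces the
#' ground-truth tables exactly.
#'
#' @param n_cows,n_days Number of cows and of sampling days per cow.
#' @param seed RNG seed.
#' @param noise Relative SD of measurement noise applied to observed
#'   records (0 disables it).
#' @param parameters Parameter list from [animal_parameters()].
#' @param treatments Treatment labels cycled over cows.
#' @return List with `records` (observed tibble, one row per cow-day),
#'   `truth` (list: `records` noise-free tibble, `balance` the true balance
#'   table from [nutrient_balance()]).
#' @export
simulate_animal_days <- function(n_cows = 6, n_days = 4, seed = 1L,
                                 noise = 0.02,
                                 parameters = animal_parameters(),
                                 treatments = c("CG", "SH")) {
  if (n_cows < 1 || n_days < 1) {
    abort("`n_cows` and `n_days` must be at least 1.")
  }
  if (noise < 0) abort("`noise` must be non-negative.")
  p <- parameters

  with_seed(seed, {
    n_resampled <- 0L
    log_resample <- function(k) n_resampled <<- n_resampled + k

    cows <- tibble::tibble(
      cow_id = sprintf("cow%02d", seq_len(n_cows)),
      treatment = rep_len(treatments, n_cows),
      dmi_base = runif(n_cows, p$dmi_range_kg_d[1], p$dmi_range_kg_d[2]),
      dmd_pct = rnorm_pos(n_cows, p$dmd_pct, log_resample),
      ged_pct = rnorm_pos(n_cows, p$ged_pct, log_resample),
      ndfd_pct = rnorm_pos(n_cows, p$ndfd_pct, log_resample),
      milk_base = rnorm_pos(n_cows, p$milk_kg_d, log_resample),
      fat_pct = rnorm_pos(n_cows, p$fat_pct, log_resample),
      protein_pct = rnorm_pos(n_cows, p$protein_pct, log_resample),
      lactose_pct = rnorm_pos(n_cows, p$lactose_pct, log_resample),
      ch4_yield = rnorm_pos(n_cows, p$ch4_yield_g_kg, log_resample),
      fecal_n_frac = rnorm_pos(n_cows, p$fecal_n_frac_intake, log_resample),
      urinary_n_frac = rnorm_pos(n_cows, p$urinary_n_frac_intake, log_resample),
      creatinine = rnorm_pos(n_cows, p$urine_creatinine_mg_l, log_resample),
      bw_kg = rnorm_pos(n_cows, p$bw_kg, log_resample),
      bcs = pmin(5, pmax(1, round(rnorm(n_cows, p$bcs[["mean"]], p$bcs[["sd"]]) / 0.25) * 0.25))
    )

    truth <- tidyr::expand_grid(cows, day = seq_len(n_days)) |>
      dplyr::mutate(
        dmi_kg_d = .data$dmi_base * (1 + rnorm(dplyr::n(), sd = p$day_cv)),
        milk_kg_d = .data$milk_base * (1 + rnorm(dplyr::n(), sd = p$day_cv)),
        cp_frac = p$cp_frac,
        ndf_frac = p$ndf_frac,
        ndfi_frac = p$ndfi_frac,
        ge_mj_kg = p$ge_mj_kg,
        fat_kg_d = .data$milk_kg_d * .data$fat_pct / 100,
        protein_kg_d = .data$milk_kg_d * .data$protein_pct / 100,
        lactose_kg_d = .data$milk_kg_d * .data$lactose_pct / 100,
        milk_n_g_d = .data$protein_kg_d / 6.38 * 1000,
        n_intake_g_d = .data$dmi_kg_d * .data$cp_frac / 6.25 * 1000,
        gei_mj_d = .data$dmi_kg_d * .data$ge_mj_kg,
        fecal_dm_kg_d = .data$dmi_kg_d * (1 - .data$dmd_pct / 100),
        fecal_ndfi_g_kg = .data$dmi_kg_d * .data$ndfi_frac * 1000 / .data$fecal_dm_kg_d,
        fecal_ndf_g_kg = .data$dmi_kg_d * .data$ndf_frac * 1000 *
          (1 - .data$ndfd_pct / 100) / .data$fecal_dm_kg_d,
        fecal_ge_mj_kg = .data$gei_mj_d * (1 - .data$ged_pct / 100) / .data$fecal_dm_kg_d,
        fecal_n_pct = .data$fecal_n_frac * .data$n_intake_g_d /
          (.data$fecal_dm_kg_d * 1000) * 100,
        urine_creatinine_mg_l = .data$creatinine,
        urine_l_d = 29 * .data$bw_kg / .data$urine_creatinine_mg_l,
        urine_n_g_l = .data$urinary_n_frac * .data$n_intake_g_d / .data$urine_l_d,
        ch4_g_d = .data$ch4_yield * .data$dmi_kg_d
      )

    record_cols <- c(
      "cow_id", "treatment", "day",
      "dmi_kg_d", "cp_frac", "ndf_frac", "ndfi_frac", "ge_mj_kg",
      "milk_kg_d", "fat_kg_d", "protein_kg_d", "lactose_kg_d", "milk_n_g_d",
      "fecal_ndfi_g_kg", "fecal_ndf_g_kg", "fecal_ge_mj_kg", "fecal_n_pct",
      "urine_creatinine_mg_l", "urine_n_g_l", "bw_kg", "bcs", "ch4_g_d"
    )
    truth_records <- truth[record_cols]

    observed <- truth_records
    if (noise > 0) {
      noisy_cols <- c(
        "dmi_kg_d", "milk_kg_d", "fat_kg_d", "protein_kg_d", "lactose_kg_d",
        "milk_n_g_d", "fecal_ndfi_g_kg", "fecal_ndf_g_kg", "fecal_ge_mj_kg",
        "fecal_n_pct", "urine_creatinine_mg_l", "urine_n_g_l", "bw_kg",
        "ch4_g_d"
      )
      for (col in noisy_cols) {
        mult <- pmax(1 + rnorm(nrow(observed), sd = noise), 1e-3)
        observed[[col]] <- observed[[col]] * mult
      }
    }
    if (n_resampled > 0) {
      inform(paste0(n_resampled, " draw(s) produced non-positive values and were resampled."))
    }

    list(
      records = observed,
      truth = list(
        records = truth_records,
        balance = nutrient_balance(truth_records)
      )
    )
  })
}
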