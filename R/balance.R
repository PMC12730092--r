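#' Fat-corrected and energy-corrected milk
#'
#' Linear standardizations of milk yield by component yields:
#' `FCM = 0.4 milk + 15 fat` and
#' `ECM = 12.95 fat + 7.2 protein + 0.327 milk` (all kg/d).
#'
#' @param milk_kg_d,fat_kg_d,protein_kg_d Milk and component yields, kg/d.
#' @return kg/d, vectorized.
#' @examples
#' fcm(39.82, 1.35)
#' ecm(39.82, 1.35, 1.31)
#' @export
fcm <- function(milk_kg_d, fat_kg_d) {
  if (any(milk_kg_d < 0 | fat_kg_d < 0, na.rm = TRUE)) {
    abort("Milk and fat yields must be non-negative.")
  }
  0.4 * milk_kg_d + 15 * fat_kg_d
}

#' @rdname fcm
#' @export
ecm <- function(milk_kg_d, fat_kg_d, protein_kg_d) {
  if (any(milk_kg_d < 0 | fat_kg_d < 0 | protein_kg_d < 0, na.rm = TRUE)) {
    abort("Milk and component yields must be non-negative.")
  }
  12.95 * fat_kg_d + 7.2 * protein_kg_d + 0.327 * milk_kg_d
}

#' Total fecal output from an internal marker
#'
#' With an indigestible marker fully recovered in feces, fecal dry matter
#' output is the marker intake divided by its concentration in fecal DM.
#'
#' @param marker_intake Marker intake per day (g/d for NDFi or NDF, MJ/d for
#'   gross energy).
#' @param fecal_marker_conc Marker concentration per kg fecal DM, same
#'   numerator unit as `marker_intake` (g/kg or MJ/kg).
#' @return Fecal output, kg DM/d.
#' @examples
#' marker_fecal_output(2400, 300)
#' @export
marker_fecal_output <- function(marker_intake, fecal_marker_conc) {
  if (any(fecal_marker_conc <= 0, na.rm = TRUE)) {
    abort("`fecal_marker_conc` must be positive.")
  }
  if (any(marker_intake < 0, na.rm = TRUE)) {
    abort("`marker_intake` must be non-negative.")
  }
  marker_intake / fecal_marker_conc
}

#' Apparent total-tract digestibility
#'
#' `(intake - fecal output) / intake * 100`, applied identically to DM, NDF
#' and GE with their respective intakes and fecal quantities.
#'
#' @param intake Daily intake (kg/d or MJ/d).
#' @param fecal_output Daily fecal output, same unit.
#' @return Digestibility, percent.
#' @examples
#' apparent_digestibility(25, 8)
#' @export
apparent_digestibility <- function(intake, fecal_output) {
  if (any(intake <= 0, na.rm = TRUE)) {
    abort("`intake` must be positive.")
  }
  (intake - fecal_output) / intake * 100
}

#' Urine volume from spot-sample creatinine
#'
#' Assumes a constant creatinine excretion per kg body weight (29 mg/kg/d):
#' daily volume is that excretion divided by the spot-sample concentration.
#'
#' @param bw_kg Body weight, kg.
#' @param urine_creatinine_mg_l Urinary creatinine concentration, mg/L.
#' @param excretion_mg_kg Assumed creatinine excretion, mg per kg BW per day.
#' @return Urine volume, L/d.
#' @examples
#' urine_volume(600, 1200)
#' @export
urine_volume <- function(bw_kg, urine_creatinine_mg_l, excretion_mg_kg = 29) {
  if (any(urine_creatinine_mg_l <= 0, na.rm = TRUE)) {
    abort("`urine_creatinine_mg_l` must be positive.")
  }
  excretion_mg_kg * bw_kg / urine_creatinine_mg_l
}

#' Nitrogen partition and nitrogen-use efficiency
#'
#' Partitions intake N into fecal, urinary, milk and retained fractions:
#' total excretion = fecal + urinary; retained = intake - total excretion;
#' productive = retained + milk; NUE = milk N / intake N. Each component is
#' also returned as a percentage of intake N.
#'
#' @param intake_n,fecal_n,urinary_n,milk_n Daily N flows, g/d (vectorized).
#' @return Tibble with the partition in g/d, percentages of intake N, and
#'   `nue` as a fraction.
#' @examples
#' nitrogen_balance(1000, 240, 390, 200)
#' @export
nitrogen_balance <- function(intake_n, fecal_n, urinary_n, milk_n) {
  if (any(c(intake_n, fecal_n, urinary_n, milk_n) < 0, na.rm = TRUE)) {
    abort("All nitrogen flows must be non-negative.")
  }
  if (any(intake_n == 0 & (fecal_n + urinary_n + milk_n) > 0, na.rm = TRUE)) {
    abort("Zero N intake with non-zero N outputs is inconsistent.")
  }
  total <- fecal_n + urinary_n
  retained <- intake_n - total
  productive <- retained + milk_n
  pct <- function(x) ifelse(intake_n > 0, 100 * x / intake_n, 0)
  tibble::tibble(
    intake_n = intake_n,
    fecal_n = fecal_n,
    urinary_n = urinary_n,
    total_excretion_n = total,
    milk_n = milk_n,
    retained_n = retained,
    productive_n = productive,
    nue = ifelse(intake_n > 0, milk_n / intake_n, 0),
    fecal_n_pct = pct(fecal_n),
    urinary_n_pct = pct(urinary_n),
    total_excretion_n_pct = pct(total),
    milk_n_pct = pct(milk_n),
    retained_n_pct = pct(retained),
    productive_n_pct = pct(productive)
  )
}

#' Energy partition from gross to metabolizable energy
#'
#' Losses from gross energy intake (GEI): fecal energy gives digestible
#' energy `DE = GEI - E_feces`; methane energy is `0.0556 MJ/g CH4`;
#' urinary energy is taken as 4% of GEI; milk energy is computed from
#' component yields (default 39.32, 23.84 and 16.73 MJ/kg of fat, protein
#' and lactose). Metabolizable energy defaults to the conventional
#' `ME = DE - E_methane - E_urine`; `me_mode = "absorbed"` instead uses
#' milk + body energy ("absorbed") plus methane ("fermented") minus urinary
#' energy. Energy balance is `EB = ME - 0.08 BW^0.75 - E_milk` and energy-use
#' efficiency `EUE = E_milk / GEI`.
#'
#' @param gei_mj_d Gross energy intake, MJ/d.
#' @param e_feces_mj_d Fecal energy, MJ/d, in `[0, gei_mj_d]`.
#' @param ch4_g_d Methane production, g/d.
#' @param fat_kg_d,protein_kg_d,lactose_kg_d Milk component yields, kg/d.
#' @param bw_kg Body weight, kg.
#' @param e_milk_coefs Named numeric: MJ/kg coefficients for `fat`,
#'   `protein`, `lactose`.
#' @param ch4_energy_mj_g Energy content of methane, MJ/g.
#' @param urine_energy_frac Urinary energy as a fraction of GEI.
#' @param maintenance_coef Coefficient on metabolic body weight in EB.
#' @param me_mode `"standard"` or `"absorbed"` (see Details).
#' @param e_body_mj_d Body tissue energy change, MJ/d; used only by the
#'   `"absorbed"` mode.
#' @return Tibble with `gei`, `e_feces`, `de`, `e_urine`, `e_methane`,
#'   `e_milk`, `me`, `eb`, `eue` (MJ/d; `eue` a fraction) and each loss as
#'   percent of GEI.
#' @examples
#' energy_partition(430, 200, 454, 1.35, 1.31, 2.01, 586)
#' @export
energy_partition <- function(gei_mj_d, e_feces_mj_d, ch4_g_d,
                             fat_kg_d, protein_kg_d, lactose_kg_d, bw_kg,
                             e_milk_coefs = c(fat = 39.32, protein = 23.84, lactose = 16.73),
                             ch4_energy_mj_g = 0.0556,
                             urine_energy_frac = 0.04,
                             maintenance_coef = 0.08,
                             me_mode = c("standard", "absorbed"),
                             e_body_mj_d = 0) {
  me_mode <- match.arg(me_mode)
  neg <- c(
    gei = any(gei_mj_d <= 0), e_feces = any(e_feces_mj_d < 0),
    ch4 = any(ch4_g_d < 0), fat = any(fat_kg_d < 0),
    protein = any(protein_kg_d < 0), lactose = any(lactose_kg_d < 0)
  )
  if (any(neg)) {
    abort(paste0("Negative or non-positive component(s): ",
                 paste(names(neg)[neg], collapse = ", "), "."))
  }
  # tolerance covers the degenerate gross-energy-marker case, where fecal
  # energy reconstructs GEI exactly up to rounding
  if (any(e_feces_mj_d > gei_mj_d * (1 + 1e-9))) {
    abort("`e_feces_mj_d` cannot exceed `gei_mj_d`.")
  }
  de <- gei_mj_d - e_feces_mj_d
  e_methane <- ch4_energy_mj_g * ch4_g_d
  e_urine <- urine_energy_frac * gei_mj_d
  e_milk <- e_milk_coefs[["fat"]] * fat_kg_d +
    e_milk_coefs[["protein"]] * protein_kg_d +
    e_milk_coefs[["lactose"]] * lactose_kg_d
  me <- switch(
    me_mode,
    standard = de - e_methane - e_urine,
    absorbed = (e_milk + e_body_mj_d) + e_methane - e_urine
  )
  eb <- me - maintenance_coef * bw_kg^0.75 - e_milk
  pct <- function(x) 100 * x / gei_mj_d
  tibble::tibble(
    gei = gei_mj_d,
    e_feces = e_feces_mj_d,
    de = de,
    e_urine = e_urine,
    e_methane = e_methane,
    e_milk = e_milk,
    me = me,
    eb = eb,
    eue = e_milk / gei_mj_d,
    e_feces_pct_gei = pct(e_feces_mj_d),
    e_urine_pct_gei = pct(e_urine),
    e_methane_pct_gei = pct(e_methane),
    e_milk_pct_gei = pct(e_milk)
  )
}

#' Methane yield and intensity metrics
#'
#' Methane production scaled by intake, energy and production denominators.
#'
#' @param ch4_g_d Methane production, g/d.
#' @param dmi_kg_d Dry matter intake, kg/d.
#' @param gei_mj_d,dei_mj_d Gross and digestible energy intake, MJ/d.
#' @param milk_kg_d,fcm_kg_d,ecm_kg_d Milk, FCM and ECM yields, kg/d.
#' @param fat_kg_d,protein_kg_d Milk fat and protein yields, kg/d.
#' @param ch4_energy_mj_g Energy content of methane, MJ/g.
#' @return Tibble of metrics: `g_per_day`, `g_per_kg_dmi`, `pct_gei`,
#'   `pct_dei`, `g_per_kg_milk`, `g_per_kg_fcm`, `g_per_kg_ecm`,
#'   `g_per_kg_fat`, `g_per_kg_protein`. A metric with a zero denominator is
#'   `NA` and flagged with a warning.
#' @examples
#' methane_metrics(454, 27, 430, 230, 39.8, 35.9, 39.6, 1.35, 1.31)
#' @export
methane_metrics <- function(ch4_g_d, dmi_kg_d, gei_mj_d, dei_mj_d,
                            milk_kg_d, fcm_kg_d, ecm_kg_d,
                            fat_kg_d, protein_kg_d,
                            ch4_energy_mj_g = 0.0556) {
  if (any(ch4_g_d < 0, na.rm = TRUE)) {
    abort("`ch4_g_d` must be non-negative.")
  }
  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad, na.rm = TRUE)) {
      warn(paste0("Zero denominator for ", what, "; metric set to NA."))
    }
    ifelse(bad, NA_real_, num / den)
  }
  tibble::tibble(
    g_per_day = ch4_g_d,
    g_per_kg_dmi = safe_div(ch4_g_d, dmi_kg_d, "g/kg DMI"),
    pct_gei = safe_div(100 * ch4_energy_mj_g * ch4_g_d, gei_mj_d, "% of GE intake"),
    pct_dei = safe_div(100 * ch4_energy_mj_g * ch4_g_d, dei_mj_d, "% of DE intake"),
    g_per_kg_milk = safe_div(ch4_g_d, milk_kg_d, "g/kg milk"),
    g_per_kg_fcm = safe_div(ch4_g_d, fcm_kg_d, "g/kg FCM"),
    g_per_kg_ecm = safe_div(ch4_g_d, ecm_kg_d, "g/kg ECM"),
    g_per_kg_fat = safe_div(ch4_g_d, fat_kg_d, "g/kg milk fat"),
    g_per_kg_protein = safe_div(ch4_g_d, protein_kg_d, "g/kg milk protein")
  )
}

#' Per-cow nutrient balance from raw records
#'
#' Runs the whole balance chain on a tidy table of per-cow (per-day or
#' per-period) records: marker-based fecal output and digestibility,
#' creatinine-based urine volume, nitrogen partition, energy partition, milk
#' standardizations and methane metrics. One input row yields one output
#' row; identifier columns (`cow_id`, `treatment`, `period`, `day`) are
#' carried through when present.
#'
#' @param records Tibble with columns `dmi_kg_d`, `cp_frac`, `ndf_frac`,
#'   `ndfi_frac`, `ge_mj_kg`, `milk_kg_d`, `fat_kg_d`, `protein_kg_d`,
#'   `lactose_kg_d`, `milk_n_g_d`, `fecal_ndfi_g_kg`, `fecal_ndf_g_kg`,
#'   `fecal_ge_mj_kg`, `fecal_n_pct`, `urine_creatinine_mg_l`,
#'   `urine_n_g_l`, `bw_kg`, `ch4_g_d` (see [simulate_animal_days()]).
#' @param marker Internal marker for fecal output: `"ndfi"` (default),
#'   `"ge"` or `"ndf"`.
#' @param ... Passed to [energy_partition()] (coefficients, `me_mode`).
#' @return Tibble with intake, digestibility, milk, nitrogen, energy and
#'   methane results, one row per input row.
#' @export
nutrient_balance <- function(records, marker = c("ndfi", "ge", "ndf"), ...) {
  marker <- match.arg(marker)
  records <- tibble::as_tibble(records)
  req <- c(
    "dmi_kg_d", "cp_frac", "ndf_frac", "ndfi_frac", "ge_mj_kg",
    "milk_kg_d", "fat_kg_d", "protein_kg_d", "lactose_kg_d", "milk_n_g_d",
    "fecal_ndfi_g_kg", "fecal_ndf_g_kg", "fecal_ge_mj_kg", "fecal_n_pct",
    "urine_creatinine_mg_l", "urine_n_g_l", "bw_kg", "ch4_g_d"
  )
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }

  id_cols <- intersect(c("cow_id", "treatment", "period", "day"), names(records))
  r <- records

  n_intake <- r$dmi_kg_d * r$cp_frac / 6.25 * 1000
  gei <- r$dmi_kg_d * r$ge_mj_kg
  ndf_intake_g <- r$dmi_kg_d * r$ndf_frac * 1000

  fecal_dm <- switch(
    marker,
    ndfi = marker_fecal_output(r$dmi_kg_d * r$ndfi_frac * 1000, r$fecal_ndfi_g_kg),
    ge = marker_fecal_output(gei, r$fecal_ge_mj_kg),
    ndf = marker_fecal_output(ndf_intake_g, r$fecal_ndf_g_kg)
  )
  e_feces <- fecal_dm * r$fecal_ge_mj_kg
  fecal_ndf_g <- fecal_dm * r$fecal_ndf_g_kg
  fecal_n <- fecal_dm * 1000 * r$fecal_n_pct / 100

  urine_l <- urine_volume(r$bw_kg, r$urine_creatinine_mg_l)
  urinary_n <- urine_l * r$urine_n_g_l

  nb <- nitrogen_balance(n_intake, fecal_n, urinary_n, r$milk_n_g_d)
  ep <- energy_partition(
    gei, e_feces, r$ch4_g_d,
    r$fat_kg_d, r$protein_kg_d, r$lactose_kg_d, r$bw_kg, ...
  )
  fcm_v <- fcm(r$milk_kg_d, r$fat_kg_d)
  ecm_v <- ecm(r$milk_kg_d, r$fat_kg_d, r$protein_kg_d)
  mm <- methane_metrics(
    r$ch4_g_d, r$dmi_kg_d, gei, ep$de,
    r$milk_kg_d, fcm_v, ecm_v, r$fat_kg_d, r$protein_kg_d
  )

  dplyr::bind_cols(
    r[id_cols],
    tibble::tibble(
      dmi_kg_d = r$dmi_kg_d,
      milk_kg_d = r$milk_kg_d,
      fcm_kg_d = fcm_v,
      ecm_kg_d = ecm_v,
      milk_per_dmi = r$milk_kg_d / r$dmi_kg_d,
      fcm_per_dmi = fcm_v / r$dmi_kg_d,
      ecm_per_dmi = ecm_v / r$dmi_kg_d,
      fecal_dm_kg_d = fecal_dm,
      dmd_pct = apparent_digestibility(r$dmi_kg_d, fecal_dm),
      ged_pct = apparent_digestibility(gei, e_feces),
      ndfd_pct = apparent_digestibility(ndf_intake_g, fecal_ndf_g),
      urine_l_d = urine_l
    ),
    nb,
    dplyr::rename_with(ep, ~ paste0("energy_", .x)),
    dplyr::rename_with(mm, ~ paste0("ch4_", .x))
  )
}

#' Descriptive treatment summary of a balance table
#'
#' Mean and standard error of the mean of every numeric result column,
#' grouped by treatment (or any grouping columns). Summaries are means of
#' per-cow values, not functions of means.
#'
#' @param balance_tbl Output of [nutrient_balance()].
#' @param ... Grouping columns (defaults to `treatment` when present).
#' @return Long tibble: group columns, `variable`, `mean`, `sem`, `n`.
#' @export
summarize_balance <- function(balance_tbl, ...) {
  groups <- rlang::enquos(...)
  if (length(groups) == 0 && "treatment" %in% names(balance_tbl)) {
    groups <- rlang::quos(treatment)
  }
  balance_tbl |>
    dplyr::group_by(!!!groups) |>
    dplyr::summarise(
      dplyr::across(
        dplyr::where(is.numeric),
        list(
          mean = ~ mean(.x, na.rm = TRUE),
          sem = ~ sd(.x, na.rm = TRUE) / sqrt(sum(!is.na(.x)))
        ),
        .names = "{.col}__{.fn}"
      ),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(
      cols = dplyr::matches("__(mean|sem)$"),
      names_to = c("variable", ".value"),
      names_sep = "__"
    )
}
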