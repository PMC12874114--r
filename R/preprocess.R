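#' Apply eligibility exclusions to a cohort
#'
#' Two-stage filter matching standard questionnaire-cohort practice: records
#' without written consent or a health-checkup attendance are removed first;
#' among the remainder, records whose estimated energy intake is implausible
#' (strictly below `energy_low` or strictly above `energy_high` kcal/d,
#' suggesting under- or over-reporting) are removed next. Boundary values are
#' kept. The three returned sets partition the input.
#'
#' @param records Diet record tibble.
#' @param energy_low,energy_high Plausibility window in kcal/d; defaults 600
#'   and 4000.
#' @return A list with tibbles `kept`, `excluded_consent`, `excluded_energy`.
#' @export
apply_exclusions <- function(records, energy_low = 600, energy_high = 4000) {
  if (energy_low >= energy_high) {
    stop("energy_low must be < energy_high", call. = FALSE)
  }
  records <- tibble::as_tibble(records)
  no_consent <- !records$consented | !records$attended_checkup
  excluded_consent <- records[no_consent, ]
  rest <- records[!no_consent, ]
  bad_energy <- rest$energy < energy_low | rest$energy > energy_high
  list(
    kept = rest[!bad_energy, ],
    excluded_consent = excluded_consent,
    excluded_energy = rest[bad_energy, ]
  )
}

#' Default sex-specific sugar energy percentages
#'
#' Brief diet-history questionnaires do not capture sugar intake reliably, so
#' total and added sugars are imputed as fixed sex-specific percentages of
#' energy intake taken from national survey estimates: total sugars 10.7%
#' (men) / 13.5% (women) of energy; added sugars 5.8% / 7.2%.
#'
#' @return A tibble with columns `sex`, `total_pct`, `added_pct` (percent of
#'   energy).
#' @export
default_sugar_pct <- function() {
  tibble::tibble(
    sex = c("male", "female"),
    total_pct = c(10.7, 13.5),
    added_pct = c(5.8, 7.2)
  )
}

#' Impute total and added sugar intake from energy
#'
#' Converts the sex-specific sugar energy percentages into grams per day
#' using the Atwater energy density of sugars (4 kcal/g):
#' `grams = energy * pct/100 / 4`. By construction the energy share
#' recomputed from the output equals the table percentage exactly.
#'
#' @param records Diet record tibble with `sex` and `energy` columns.
#' @param pct_table Percentage table as from [default_sugar_pct()].
#' @param kcal_per_g Energy density used for the gram conversion; default 4.
#' @return A tibble with `participant_id`, `total_sugar_g`, `added_sugar_g`.
#' @export
#' @examples
#' rec <- tibble::tibble(participant_id = "a", sex = "male", energy = 2000)
#' impute_sugars(rec)  # total 53.5 g, added 29 g
impute_sugars <- function(records, pct_table = default_sugar_pct(),
                          kcal_per_g = 4) {
  if (any(records$energy <= 0)) {
    stop("energy must be > 0 for sugar imputation", call. = FALSE)
  }
  missing_sex <- setdiff(unique(records$sex), pct_table$sex)
  if (length(missing_sex) > 0L) {
    stop("sugar percentage table has no entry for sex: ",
         paste(missing_sex, collapse = ", "), call. = FALSE)
  }
  idx <- match(records$sex, pct_table$sex)
  tibble::tibble(
    participant_id = records$participant_id,
    total_sugar_g = records$energy * pct_table$total_pct[idx] / 100 /
      kcal_per_g,
    added_sugar_g = records$energy * pct_table$added_pct[idx] / 100 /
      kcal_per_g
  )
}

#' Default Atwater coefficients (kcal/g) for the energy-percentage macros
#' @return Named numeric vector.
#' @export
default_atwater <- function() {
  c(protein = 4, fat = 9, sfa = 9, carbohydrate = 4)
}

#' Energy-adjust a cohort with the density method
#'
#' Expresses each macronutrient as a percentage of energy intake
#' (`intake_g * atwater / energy * 100`) and each micronutrient and food
#' group per 1000 kcal (`intake / energy * 1000`), the standard device for
#' attenuating correlated measurement error in questionnaire intakes. Also
#' computes the dietary sodium-to-potassium ratio on a mass (mg/mg) basis.
#' The profile is invariant to uniform scaling of energy and all intakes.
#'
#' @param records Diet record tibble (energy > 0 for all rows).
#' @param atwater Named kcal/g map for the macro columns; default
#'   [default_atwater()].
#' @return A tibble with `participant_id`, `sex`, `cohort`,
#'   `<macro>_pct_energy` columns, `<item>_per_1000kcal` columns for the
#'   remaining nutrients and all food groups, and `na_k_ratio`.
#' @export
to_density_profile <- function(records, atwater = default_atwater()) {
  records <- tibble::as_tibble(records)
  if (any(records$energy <= 0)) {
    stop("energy must be > 0 for density adjustment", call. = FALSE)
  }
  macros <- names(atwater)
  out <- tibble::tibble(
    participant_id = records$participant_id,
    sex = records$sex,
    cohort = records$cohort
  )
  for (m in macros) {
    out[[paste0(m, "_pct_energy")]] <-
      records[[m]] * atwater[[m]] / records$energy * 100
  }
  micros <- setdiff(diet_nutrients(), macros)
  for (col in c(micros, diet_food_groups())) {
    out[[paste0(col, "_per_1000kcal")]] <-
      records[[col]] / records$energy * 1000
  }
  # sodium stored in g, potassium in mg: convert to a mg/mg ratio
  out$na_k_ratio <- (records$sodium * 1000) / records$potassium
  out
}
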