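#' Shipped HEI-2015 component standards
#'
#' The 2015 Healthy Eating Index scores 13 density-based components — 9
#' adequacy (total fruits, whole fruits, total vegetables, greens and beans,
#' whole grains, dairy, total protein foods, seafood and plant proteins,
#' fatty-acid ratio) and 4 moderation (refined grains, sodium, added sugars,
#' saturated fats) — with maximum points summing to 100. Adequacy components
#' score linearly from 0 at `standard_for_min` to the maximum at or beyond
#' `standard_for_max`; moderation components score the maximum at or below
#' their healthy threshold and 0 at or beyond the worst threshold.
#'
#' Serving-based standards are expressed in serving equivalents per
#' 1000 kcal and converted from gram densities through `g_per_serving`, an
#' editable conversion column; the shipped conversions are documented
#' approximations for questionnaire data (fruit 100 g, vegetables 150 g and
#' legumes 150 g per cup-equivalent, grains 28 g and protein foods 28.35 g
#' per ounce-equivalent with 7 g protein per ounce, dairy 244 g per
#' cup-equivalent). Refined-grain intake is read from an optional
#' `refined_grains_per_1000kcal` column and treated as 0 g when absent.
#'
#' @return A tibble with columns `component`, `type`, `max_points`, `source`,
#'   `g_per_serving`, `standard_for_max`, `standard_for_min`.
#' @export
hei2015_standards <- function() {
  tibble::tribble(
    ~component,               ~type,        ~max_points, ~source,            ~g_per_serving, ~standard_for_max, ~standard_for_min,
    "total_fruits",           "adequacy",   5,  "fruits",           100,    0.8,  0,
    "whole_fruits",           "adequacy",   5,  "fruits",           100,    0.4,  0,
    "total_vegetables",       "adequacy",   5,  "vegetables",       150,    1.1,  0,
    "greens_and_beans",       "adequacy",   5,  "legumes",          150,    0.2,  0,
    "whole_grains",           "adequacy",   10, "whole_grains",     28,     1.5,  0,
    "dairy",                  "adequacy",   10, "dairy",            244,    1.3,  0,
    "total_protein_foods",    "adequacy",   5,  "protein",          7,      2.5,  0,
    "seafood_plant_proteins", "adequacy",   5,  "fish_legumes",     28.35,  0.8,  0,
    "fatty_acids",            "adequacy",   10, "fatty_acid_ratio", NA,     2.5,  1.2,
    "refined_grains",         "moderation", 10, "refined_grains",   28,     1.8,  4.3,
    "sodium",                 "moderation", 10, "sodium",           1,      1.1,  2.0,
    "added_sugars",           "moderation", 10, "added_sugars",     NA,     6.5,  26,
    "saturated_fats",         "moderation", 10, "sfa_pct",          NA,     8,    16
  )
}

# pull the raw component value (gram density, % energy, or ratio) from a
# density profile; added-sugar % energy comes from the imputation stage
hei_component_value <- function(profiles, added_sugar_energy_pct, source) {
  dens <- function(col) {
    name <- paste0(col, "_per_1000kcal")
    if (!name %in% names(profiles)) {
      if (col == "refined_grains") return(rep(0, nrow(profiles)))
      stop("density profile lacks column '", name, "'", call. = FALSE)
    }
    profiles[[name]]
  }
  switch(source,
    protein = profiles$protein_pct_energy / 100 * 1000 / 4,  # g/1000 kcal
    fatty_acid_ratio = (profiles$fat_pct_energy - profiles$sfa_pct_energy) /
      profiles$sfa_pct_energy,
    added_sugars = added_sugar_energy_pct,
    sfa_pct = profiles$sfa_pct_energy,
    fish_legumes = dens("fish") + dens("legumes"),
    dens(source)
  )
}

#' Score HEI-2015 from density profiles
#'
#' @param profiles Density profile tibble from [to_density_profile()].
#' @param added_sugar_energy_pct Added-sugar percentage of energy per
#'   participant (scalar or vector); from the sugar imputation stage.
#' @param standards Component standards as from [hei2015_standards()].
#' @param whole_grains_zero If `TRUE` (replication mode for questionnaire
#'   instruments that do not capture whole grains), whole-grain intake is
#'   forced to 0 before scoring.
#' @return A tibble with `participant_id`, one `hei_<component>` column per
#'   component, and `total` in \[0, 100\].
#' @export
score_hei2015 <- function(profiles, added_sugar_energy_pct,
                          standards = hei2015_standards(),
                          whole_grains_zero = FALSE) {
  stopifnot(nrow(standards) == 13L)
  if (!isTRUE(all.equal(sum(standards$max_points), 100))) {
    stop("HEI component maxima must sum to 100", call. = FALSE)
  }
  if (whole_grains_zero) {
    profiles$whole_grains_per_1000kcal <- 0
  }
  out <- tibble::tibble(participant_id = profiles$participant_id)
  total <- 0
  for (i in seq_len(nrow(standards))) {
    st <- standards[i, ]
    value <- hei_component_value(profiles, added_sugar_energy_pct, st$source)
    if (!is.na(st$g_per_serving)) value <- value / st$g_per_serving
    # shared linear ramp: for moderation standard_for_max < standard_for_min,
    # so the score decreases with intake
    frac <- (value - st$standard_for_min) /
      (st$standard_for_max - st$standard_for_min)
    pts <- st$max_points * pmin(pmax(frac, 0), 1)
    out[[paste0("hei_", st$component)]] <- pts
    total <- total + pts
  }
  out$total <- total
  out
}

#' Shipped NRF9.3 daily values
#'
#' Nine nutrients to encourage and three to limit. Encourage daily values
#' align with the MNPS-OA reference daily values where the two systems
#' overlap (protein 60 g, fiber 20 g, calcium 750 mg, vitamin D 8.5 ug) and
#' use dietary-reference-intake style values for the rest; maximum
#' recommended values for the limit nutrients are saturated fat 20 g, added
#' sugars 50 g and sodium 7.5 g (the package-wide sodium unit). All are
#' editable configuration, not cohort estimates.
#'
#' @param cap_pct Percent-daily-value cap applied to each encourage nutrient
#'   (default 100; `Inf` removes the cap).
#' @param basis `"per_day"` (default) or `"per_100kcal"`.
#' @return A list of class `nrf_config`.
#' @export
nrf93_config <- function(cap_pct = 100, basis = c("per_day", "per_100kcal")) {
  basis <- match.arg(basis)
  structure(
    list(
      encourage_dvs = c(protein = 60, dietary_fiber = 20, vitamin_a = 900,
                        vitamin_c = 100, vitamin_d = 8.5, calcium = 750,
                        iron = 7.5, potassium = 3000, magnesium = 350),
      limit_dvs = c(sfa = 20, added_sugar = 50, sodium = 7.5),
      cap_pct = cap_pct, basis = basis
    ),
    class = "nrf_config"
  )
}

#' Score NRF9.3
#'
#' Sum of the percent daily values (%DV) of the nine encourage nutrients,
#' each capped at `cap_pct`, minus the %DV of the three limit nutrients
#' (uncapped). On the `per_100kcal` basis every intake is first standardised
#' to 100 kcal of the participant's energy. Added-sugar grams always come
#' from the imputation stage, never from the record.
#'
#' @param records Diet record tibble.
#' @param added_sugar_g Added-sugar grams per day aligned with `records`.
#' @param config An `nrf_config`.
#' @return Numeric vector of scores (may be negative; at most `9 * cap_pct`).
#' @export
score_nrf93 <- function(records, added_sugar_g, config = nrf93_config()) {
  if (!inherits(config, "nrf_config")) {
    stop("config must be an nrf_config", call. = FALSE)
  }
  if (any(config$encourage_dvs <= 0) || any(config$limit_dvs <= 0)) {
    stop("all daily values must be > 0", call. = FALSE)
  }
  scale <- if (config$basis == "per_100kcal") 100 / records$energy else 1
  value_of <- function(name) {
    if (name == "added_sugar") added_sugar_g else records[[name]]
  }
  enc <- 0
  for (name in names(config$encourage_dvs)) {
    pct_dv <- value_of(name) * scale / config$encourage_dvs[[name]] * 100
    enc <- enc + pmin(pct_dv, config$cap_pct)
  }
  lim <- 0
  for (name in names(config$limit_dvs)) {
    lim <- lim + value_of(name) * scale / config$limit_dvs[[name]] * 100
  }
  enc - lim
}

#' DQSJ component definitions
#'
#' The Diet Quality Score for Japanese rates ten components — fruits,
#' vegetables, whole grains, dairy, nuts, legumes and fish as adequacy
#' components, and red/processed meat, sugar-sweetened beverages and sodium
#' as moderation components — each from 0 to 3 by sex-specific quartiles of
#' intake, for a total of 0 to 30. In study-replication mode, components the
#' questionnaire does not capture (whole grains, nuts) are treated as
#' non-consumption and fixed at 0 points.
#'
#' @param zero_fixed Character vector of components scored 0 regardless of
#'   intake; default `c("whole_grains", "nuts")` (replication mode). Use
#'   `character()` for the full-information score.
#' @return A list of class `dqsj_config` with `components` (tibble: `name`,
#'   `type`) and `zero_fixed`.
#' @export
dqsj_config <- function(zero_fixed = c("whole_grains", "nuts")) {
  components <- tibble::tibble(
    name = c("fruits", "vegetables", "whole_grains", "dairy", "nuts",
             "legumes", "fish", "red_processed_meat",
             "sugar_sweetened_beverages", "sodium"),
    type = c(rep("adequacy", 7), rep("moderation", 3))
  )
  bad <- setdiff(zero_fixed, components$name)
  if (length(bad) > 0L) {
    stop("unknown zero-fixed component(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(components = components, zero_fixed = zero_fixed),
            class = "dqsj_config")
}

# stratum of each value against sex-specific quartile boundaries; the
# boundaries are order statistics (inverse-ECDF quantiles) so the stratum is
# a pure rank function: ties at a boundary fall to the lower stratum
dqsj_stratum <- function(x, sex) {
  stratum <- integer(length(x))
  for (s in unique(sex)) {
    idx <- sex == s
    q <- stats::quantile(x[idx], c(0.25, 0.5, 0.75), type = 1, names = FALSE)
    stratum[idx] <- (x[idx] > q[1]) + (x[idx] > q[2]) + (x[idx] > q[3])
  }
  stratum
}

#' Score the DQSJ across a cohort
#'
#' Component intakes are energy-adjusted densities (per 1000 kcal), cut at
#' sex-specific quartile boundaries; adequacy components score 0–3 ascending
#' with intake, moderation components 3–0. Because the boundaries are order
#' statistics, the score is invariant to any strictly increasing transform
#' of a component's intakes.
#'
#' @param profiles Density profile tibble (with `sex`); needs at least 8
#'   participants of each sex present so quartiles are definable.
#' @param config A [dqsj_config()].
#' @return A tibble with `participant_id`, `dqsj_<component>` columns, and
#'   `total` in \[0, 30\].
#' @export
score_dqsj <- function(profiles, config = dqsj_config()) {
  if (!inherits(config, "dqsj_config")) {
    stop("config must be a dqsj_config", call. = FALSE)
  }
  counts <- table(profiles$sex)
  if (any(counts < 8L)) {
    stop("DQSJ requires at least 8 participants per sex", call. = FALSE)
  }
  out <- tibble::tibble(participant_id = profiles$participant_id)
  total <- 0
  for (i in seq_len(nrow(config$components))) {
    comp <- config$components[i, ]
    if (comp$name %in% config$zero_fixed) {
      pts <- rep(0L, nrow(profiles))
    } else {
      x <- profiles[[paste0(comp$name, "_per_1000kcal")]]
      stratum <- dqsj_stratum(x, profiles$sex)
      pts <- if (comp$type == "adequacy") stratum else 3L - stratum
    }
    out[[paste0("dqsj_", comp$name)]] <- pts
    total <- total + pts
  }
  out$total <- total
  out
}
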