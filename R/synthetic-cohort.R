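#' Specification for a synthetic questionnaire-style cohort
#'
#' Builds the parameter object consumed by [generate_cohort()]. The generator
#' emulates the statistical structure of daily-intake estimates from a brief
#' diet-history questionnaire: right-skewed intakes, nutrient intakes that
#' co-vary with energy, sex-specific labels, a cohort split, and a small
#' number of ineligible records (non-consenting participants and implausible
#' energies).
#'
#' Nutrient and food-group laws are specified on the *density* scale (amount
#' per 1000 kcal): each participant draws a lognormal density whose log
#' correlates with the participant's log energy through a Gaussian copula,
#' and daily intake is density × energy / 1000. Generating on the density
#' scale and multiplying by energy reproduces the intake–energy confounding
#' that motivates density-method energy adjustment. Food-group laws may add a
#' point mass at zero (`p_zero`) for episodically consumed groups.
#'
#' @param n_participants Number of records to generate.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   spec including this seed.
#' @param sex_ratio Fraction male.
#' @param cohort_split Fraction assigned to the hatoyama cohort label.
#' @param energy_law Numeric vector `c(log_mean, log_sd)` of a lognormal for
#'   energy in kcal/d.
#' @param nutrient_laws Data frame with columns `name`, `log_mean`, `log_sd`,
#'   `rho` (copula correlation of log density with log energy), covering all
#'   of [diet_nutrients()].
#' @param food_group_laws As `nutrient_laws` plus a `p_zero` column, covering
#'   all of [diet_food_groups()].
#' @param n_no_consent Number of records flagged `consented = FALSE`.
#' @param n_energy_outliers Number of consenting records whose energy is
#'   drawn outside the plausibility window (below `energy_low` or above
#'   `energy_high`); all remaining energies fall strictly inside it.
#' @param energy_low,energy_high Plausibility window in kcal/d (default
#'   600–4000).
#' @param age_range Integer range from which ages are drawn uniformly.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants, seed,
                        sex_ratio = 0.5, cohort_split = 0.5,
                        energy_law = c(log(1900), 0.20),
                        nutrient_laws = default_nutrient_laws(),
                        food_group_laws = default_food_group_laws(),
                        n_no_consent = 0L, n_energy_outliers = 0L,
                        energy_low = 600, energy_high = 4000,
                        age_range = c(65L, 90L)) {
  n_participants <- as.integer(n_participants)
  if (n_no_consent + n_energy_outliers >= n_participants) {
    stop("n_no_consent + n_energy_outliers must be < n_participants",
         call. = FALSE)
  }
  stopifnot(energy_law[2] >= 0, sex_ratio >= 0, sex_ratio <= 1,
            cohort_split >= 0, cohort_split <= 1)
  nutrient_laws <- tibble::as_tibble(nutrient_laws)
  food_group_laws <- tibble::as_tibble(food_group_laws)
  missing_n <- setdiff(diet_nutrients(), nutrient_laws$name)
  missing_f <- setdiff(diet_food_groups(), food_group_laws$name)
  if (length(missing_n) > 0L || length(missing_f) > 0L) {
    stop("laws missing for: ",
         paste(c(missing_n, missing_f), collapse = ", "), call. = FALSE)
  }
  if (any(nutrient_laws$log_sd < 0) || any(food_group_laws$log_sd < 0)) {
    stop("all log_sd must be >= 0", call. = FALSE)
  }
  if (any(abs(nutrient_laws$rho) > 1) || any(abs(food_group_laws$rho) > 1)) {
    stop("all rho must lie in [-1, 1]", call. = FALSE)
  }
  if (any(food_group_laws$p_zero < 0 | food_group_laws$p_zero > 1)) {
    stop("zero-inflation probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_participants = n_participants, seed = as.integer(seed),
         sex_ratio = sex_ratio, cohort_split = cohort_split,
         energy_law = energy_law, nutrient_laws = nutrient_laws,
         food_group_laws = food_group_laws,
         n_no_consent = as.integer(n_no_consent),
         n_energy_outliers = as.integer(n_energy_outliers),
         energy_low = energy_low, energy_high = energy_high,
         age_range = as.integer(age_range)),
    class = "cohort_spec"
  )
}

#' Default intake laws for an older-adult Japanese-like cohort
#'
#' Per-1000-kcal density laws chosen to place median daily intakes near
#' published national-survey levels for Japanese adults aged 65 and over.
#' They are synthetic plausibility settings, not estimates from any cohort.
#'
#' @return A tibble with columns `name`, `log_mean`, `log_sd`, `rho`
#'   (and `p_zero` for food groups).
#' @export
default_nutrient_laws <- function() {
  tribble_laws <- function(name, median_density, log_sd, rho) {
    tibble::tibble(name = name, log_mean = log(median_density),
                   log_sd = log_sd, rho = rho)
  }
  dplyr::bind_rows(
    tribble_laws("protein",       38,   0.18, 0.15),
    tribble_laws("fat",           28,   0.22, 0.10),
    tribble_laws("sfa",            8,   0.25, 0.10),
    tribble_laws("carbohydrate", 135,   0.12, -0.10),
    tribble_laws("dietary_fiber",  7,   0.30, 0.05),
    tribble_laws("vitamin_a",    350,   0.45, 0.05),
    tribble_laws("vitamin_d",      6,   0.60, 0.10),
    tribble_laws("vitamin_e",      4,   0.25, 0.05),
    tribble_laws("vitamin_k",    120,   0.45, 0.05),
    tribble_laws("vitamin_b1",   0.45,  0.22, 0.10),
    tribble_laws("vitamin_b2",   0.65,  0.25, 0.10),
    tribble_laws("niacin",         8,   0.25, 0.10),
    tribble_laws("vitamin_b6",   0.70,  0.25, 0.05),
    tribble_laws("vitamin_b12",    4,   0.55, 0.10),
    tribble_laws("folate",       180,   0.35, 0.05),
    tribble_laws("vitamin_c",     60,   0.40, 0.05),
    tribble_laws("potassium",   1300,   0.25, 0.05),
    tribble_laws("calcium",      300,   0.35, 0.10),
    tribble_laws("magnesium",    140,   0.20, 0.05),
    tribble_laws("phosphorus",   550,   0.18, 0.10),
    tribble_laws("iron",         4.2,   0.22, 0.05),
    tribble_laws("zinc",         4.5,   0.18, 0.10),
    tribble_laws("copper",       0.6,   0.18, 0.05),
    tribble_laws("sodium",       2.4,   0.25, 0.10)
  )
}

#' @rdname default_nutrient_laws
#' @export
default_food_group_laws <- function() {
  row <- function(name, median_density, log_sd, rho, p_zero) {
    tibble::tibble(name = name, log_mean = log(median_density),
                   log_sd = log_sd, rho = rho, p_zero = p_zero)
  }
  dplyr::bind_rows(
    row("fruits",                     60, 0.60, 0.05, 0.10),
    row("vegetables",                140, 0.40, 0.05, 0.00),
    row("nuts",                        3, 0.80, 0.00, 0.50),
    row("legumes",                    30, 0.55, 0.05, 0.05),
    row("dairy",                      70, 0.60, 0.05, 0.15),
    row("whole_grains",                5, 0.80, 0.00, 0.60),
    row("fish",                       40, 0.50, 0.10, 0.05),
    row("red_processed_meat",         30, 0.55, 0.10, 0.05),
    row("sugar_sweetened_beverages",  30, 0.70, 0.00, 0.40)
  )
}

#' Shipped default cohort specification
#'
#' @param n Number of participants (>= 10).
#' @param seed Integer seed.
#' @param ... Overrides passed on to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
default_spec <- function(n, seed, ...) {
  if (n < 10) stop("default_spec requires n >= 10", call. = FALSE)
  cohort_spec(n_participants = n, seed = seed, ...)
}

#' Generate a synthetic cohort of diet records
#'
#' Deterministic given the spec (including its seed). Exactly
#' `spec$n_no_consent` records are flagged non-consenting and exactly
#' `spec$n_energy_outliers` consenting records receive an energy outside the
#' plausibility window; all other energies fall strictly inside it (drawn by
#' rejection from the lognormal energy law).
#'
#' @param spec A [cohort_spec()].
#' @return A validated tibble of diet records.
#' @export
#' @examples
#' cohort <- generate_cohort(default_spec(200, seed = 1))
#' dplyr::glimpse(cohort[, 1:8])
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    stop("spec must be a cohort_spec", call. = FALSE)
  }
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n_participants
  mu_e <- spec$energy_law[1]
  sd_e <- spec$energy_law[2]

  # energy: standard-normal score retained to drive the copula
  z_energy <- stats::rnorm(n)
  energy <- exp(mu_e + sd_e * z_energy)
  inside <- function(e) e > spec$energy_low & e < spec$energy_high
  # rejection: redraw any in-range candidate that fell outside the window
  bad <- which(!inside(energy))
  while (length(bad) > 0L) {
    z_energy[bad] <- stats::rnorm(length(bad))
    energy[bad] <- exp(mu_e + sd_e * z_energy[bad])
    bad <- bad[!inside(energy[bad])]
  }

  sex <- ifelse(stats::runif(n) < spec$sex_ratio, "male", "female")
  cohort <- ifelse(stats::runif(n) < spec$cohort_split,
                   "hatoyama", "kusatsu")
  age <- sample(seq(spec$age_range[1], spec$age_range[2]), n, replace = TRUE)

  draw_density <- function(law) {
    z <- law$rho * z_energy +
      sqrt(1 - law$rho^2) * stats::rnorm(n)
    exp(law$log_mean + law$log_sd * z)
  }

  out <- tibble::tibble(
    participant_id = sprintf("P%05d", seq_len(n)),
    cohort = cohort, sex = sex, age = age, energy = energy,
    consented = TRUE, attended_checkup = TRUE
  )
  for (i in seq_len(nrow(spec$nutrient_laws))) {
    law <- spec$nutrient_laws[i, ]
    out[[law$name]] <- draw_density(law) * energy / 1000
  }
  for (i in seq_len(nrow(spec$food_group_laws))) {
    law <- spec$food_group_laws[i, ]
    dens <- draw_density(law)
    zero <- stats::runif(n) < law$p_zero
    out[[law$name]] <- ifelse(zero, 0, dens * energy / 1000)
  }

  # ineligible records: non-consenters first, then energy outliers among
  # the remaining (consenting) records
  idx <- sample.int(n, spec$n_no_consent + spec$n_energy_outliers)
  no_consent <- idx[seq_len(spec$n_no_consent)]
  outliers <- setdiff(idx, no_consent)
  out$consented[no_consent] <- FALSE
  if (length(outliers) > 0L) {
    low_side <- stats::runif(length(outliers)) < 0.5
    e_out <- ifelse(low_side,
                    stats::runif(length(outliers), 300, spec$energy_low - 1),
                    stats::runif(length(outliers), spec$energy_high + 1,
                                 spec$energy_high + 1000))
    scale <- e_out / out$energy[outliers]
    out$energy[outliers] <- e_out
    # keep densities unchanged so outliers remain internally consistent
    for (col in c(diet_nutrients(), diet_food_groups())) {
      out[[col]][outliers] <- out[[col]][outliers] * scale
    }
  }
  validate_diet_records(out)
}
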