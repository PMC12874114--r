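#' Nutrient and food-group columns of a diet record
#'
#' A diet record table carries one row per participant with daily intakes as
#' estimated by a brief diet-history questionnaire: total energy (kcal/d), 23
#' nutrients (each in its conventional unit), and nine food groups in g/d.
#' `diet_nutrients()` and `diet_food_groups()` return the required column
#' names; `nutrient_units()` maps each nutrient to its unit. Sodium is carried
#' in grams throughout the package because the profiling system's reference
#' daily value for sodium is expressed in grams; use the `sodium_unit` schema
#' flag of [read_diet_records()] for sources reporting milligrams.
#'
#' @return Character vector of column names (or a named character vector of
#'   units for `nutrient_units()`).
#' @export
diet_nutrients <- function() {
  c("protein", "fat", "sfa", "carbohydrate", "dietary_fiber",
    "vitamin_a", "vitamin_d", "vitamin_e", "vitamin_k",
    "vitamin_b1", "vitamin_b2", "niacin", "vitamin_b6", "vitamin_b12",
    "folate", "vitamin_c",
    "potassium", "calcium", "magnesium", "phosphorus",
    "iron", "zinc", "copper", "sodium")
}

#' @rdname diet_nutrients
#' @export
diet_food_groups <- function() {
  c("fruits", "vegetables", "nuts", "legumes", "dairy",
    "whole_grains", "fish", "red_processed_meat",
    "sugar_sweetened_beverages")
}

#' @rdname diet_nutrients
#' @export
nutrient_units <- function() {
  c(protein = "g", fat = "g", sfa = "g", carbohydrate = "g",
    dietary_fiber = "g", vitamin_a = "ugRAE", vitamin_d = "ug",
    vitamin_e = "mg", vitamin_k = "ug", vitamin_b1 = "mg",
    vitamin_b2 = "mg", niacin = "mgNE", vitamin_b6 = "mg",
    vitamin_b12 = "ug", folate = "ug", vitamin_c = "mg",
    potassium = "mg", calcium = "mg", magnesium = "mg",
    phosphorus = "mg", iron = "mg", zinc = "mg", copper = "mg",
    sodium = "g")
}

# demographic / eligibility columns every record table must carry
diet_meta_cols <- function() {
  c("participant_id", "cohort", "sex", "age", "energy",
    "consented", "attended_checkup")
}

#' Validate a table of diet records
#'
#' Checks that all required columns are present, that energy is strictly
#' positive, that all intakes are non-negative, and that the categorical
#' fields take their allowed values (`cohort` in hatoyama/kusatsu, `sex` in
#' male/female).
#'
#' @param records A data frame of diet records (one row per participant).
#' @return The validated records as a tibble, invisibly usable downstream.
#' @export
validate_diet_records <- function(records) {
  records <- tibble::as_tibble(records)
  required <- c(diet_meta_cols(), diet_nutrients(), diet_food_groups())
  missing <- setdiff(required, names(records))
  if (length(missing) > 0L) {
    stop("diet record table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(records$cohort %in% c("hatoyama", "kusatsu"))) {
    stop("cohort must be 'hatoyama' or 'kusatsu'", call. = FALSE)
  }
  if (!all(records$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  if (any(records$age < 0)) {
    stop("age must be non-negative", call. = FALSE)
  }
  bad_energy <- which(!is.finite(records$energy) | records$energy <= 0)
  if (length(bad_energy) > 0L) {
    stop("energy must be > 0; violated at row(s) ",
         paste(utils::head(bad_energy, 5L), collapse = ", "), call. = FALSE)
  }
  for (col in c(diet_nutrients(), diet_food_groups())) {
    bad <- which(!is.finite(records[[col]]) | records[[col]] < 0)
    if (length(bad) > 0L) {
      stop("negative or missing intake in column '", col, "' at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
  }
  records
}

#' Read diet records from a delimited file
#'
#' Reads a CSV/TSV with one row per participant, renames columns according to
#' a schema mapping, applies unit coercion, and validates the result.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Optional schema: a list with elements
#'   \describe{
#'     \item{columns}{named character vector mapping package column name ->
#'       file column name, for files whose headers differ from the canonical
#'       names; unmapped canonical names are looked up verbatim.}
#'     \item{sodium_unit}{`"g"` (default) or `"mg"`; with `"mg"` the sodium
#'       column is divided by 1000 on read so sodium is stored in grams.}
#'   }
#'   May also be a path to a YAML file with the same structure.
#' @param delim Field delimiter, default `","`.
#' @return A validated tibble of diet records.
#' @export
read_diet_records <- function(path, schema = NULL, delim = ",") {
  if (is.character(schema) && length(schema) == 1L) {
    schema <- yaml::read_yaml(schema)
  }
  schema <- schema %||% list()
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  mapping <- schema$columns
  if (!is.null(mapping)) {
    missing_src <- setdiff(unname(mapping), names(raw))
    if (length(missing_src) > 0L) {
      stop("schema names column(s) absent from file: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    for (dst in names(mapping)) {
      names(raw)[names(raw) == mapping[[dst]]] <- dst
    }
  }
  required <- c(diet_meta_cols(), diet_nutrients(), diet_food_groups())
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("input file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (identical(schema$sodium_unit %||% "g", "mg")) {
    raw$sodium <- raw$sodium / 1000
  }
  raw$consented <- as.logical(raw$consented)
  raw$attended_checkup <- as.logical(raw$attended_checkup)
  validate_diet_records(raw[, required])
}

#' Write a score panel (or any per-participant table) to CSV
#'
#' Writes one row per participant with a stable column order and full float
#' precision, so that a write/read round trip preserves scores to numerical
#' accuracy.
#'
#' @param panels A non-empty data frame of per-participant scores.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(panels, path) {
  if (!is.data.frame(panels) || nrow(panels) == 0L) {
    stop("score panel must be a non-empty data frame", call. = FALSE)
  }
  readr::write_csv(panels, path)
  invisible(path)
}

#' @importFrom rlang %||%
NULL
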