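#' Points for one encourage item
#'
#' Points accrue linearly with intake relative to the reference daily value
#' (RDV) and saturate at the item's creditable cap:
#' `points = 100 * min(intake / rdv, cap_fraction)`. Continuous,
#' nondecreasing in intake, and constant at `100 * cap_fraction` beyond the
#' cap. With `cap_fraction = 1` an intake at exactly the RDV earns 100
#' points.
#'
#' @param intake Daily intake in the item's unit (vectorised, >= 0).
#' @param rdv Reference daily value (> 0).
#' @param cap_fraction Creditable cap as a fraction of the RDV, in (0, 1].
#' @return Points (same length as `intake`).
#' @export
score_encourage_item <- function(intake, rdv, cap_fraction = 1) {
  if (any(rdv <= 0)) stop("rdv must be > 0", call. = FALSE)
  if (any(cap_fraction <= 0 | cap_fraction > 1)) {
    stop("cap_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (any(intake < 0)) stop("intake must be >= 0", call. = FALSE)
  100 * pmin(intake / rdv, cap_fraction)
}

#' Deduction for one limit item
#'
#' Deductions scale linearly with intake from zero, unbounded above:
#' `deduction = 100 * intake / rdv`. An intake at exactly the RDV costs 100
#' points.
#'
#' @inheritParams score_encourage_item
#' @return Deduction points (>= 0).
#' @export
score_limit_item <- function(intake, rdv) {
  if (any(rdv <= 0)) stop("rdv must be > 0", call. = FALSE)
  if (any(intake < 0)) stop("intake must be >= 0", call. = FALSE)
  100 * intake / rdv
}

#' Score a cohort under one MNPS-OA variant
#'
#' Applies [score_encourage_item()] over the variant's nine encourage items
#' and [score_limit_item()] over its limit set (energy is omitted for the
#' without-energy-limit variants), and returns a per-participant breakdown.
#' The total is the sum of encourage points minus the sum of deductions; it
#' is not floored at zero, so the full range is available to rank-based
#' validity analyses. Sugar intake is never read from the record — brief
#' diet-history questionnaires cannot capture it — and must be supplied from
#' [impute_sugars()].
#'
#' @param records Diet record tibble (post-exclusion).
#' @param sugar_g Numeric vector of total-sugar grams per day, aligned with
#'   `records` rows (from [impute_sugars()]).
#' @param config An `mnps_profile` from [load_profile_config()].
#' @return A tibble with `participant_id`, one `enc_<item>` column per
#'   encourage item, one `ded_<item>` column per limit item, and `total`;
#'   attribute `variant` carries the variant name.
#' @export
score_mnps <- function(records, sugar_g, config) {
  if (!inherits(config, "mnps_profile")) {
    stop("config must be an mnps_profile", call. = FALSE)
  }
  records <- tibble::as_tibble(records)
  if (length(sugar_g) != nrow(records)) {
    stop("sugar_g must align with records rows", call. = FALSE)
  }
  item_value <- function(name) {
    switch(name,
      energy = records$energy,
      sugar = sugar_g,
      {
        if (!name %in% names(records)) {
          stop("record table lacks scored item '", name, "'", call. = FALSE)
        }
        records[[name]]
      }
    )
  }
  out <- tibble::tibble(participant_id = records$participant_id)
  enc_total <- 0
  for (i in seq_len(nrow(config$encourage_items))) {
    it <- config$encourage_items[i, ]
    pts <- score_encourage_item(item_value(it$name), it$rdv, it$cap_fraction)
    out[[paste0("enc_", it$name)]] <- pts
    enc_total <- enc_total + pts
  }
  ded_total <- 0
  for (i in seq_len(nrow(config$limit_items))) {
    it <- config$limit_items[i, ]
    ded <- score_limit_item(item_value(it$name), it$rdv)
    out[[paste0("ded_", it$name)]] <- ded
    ded_total <- ded_total + ded
  }
  out$total <- enc_total - ded_total
  attr(out, "variant") <- config$variant
  out
}

#' Score a cohort under all four MNPS-OA variants
#'
#' Convenience wrapper over [score_mnps()]; for every record the totals obey
#' the ordering original <= wel, original <= wc, wel <= wel_wc and
#' wc <= wel_wc, because the modified variants only remove deductions or
#' relax caps.
#'
#' @inheritParams score_mnps
#' @param profile_path Optional path to an alternative profiles YAML.
#' @return A tibble with `participant_id`, `mnps_original`, `mnps_wel`,
#'   `mnps_wc`, `mnps_wel_wc`.
#' @export
score_all_variants <- function(records, sugar_g, profile_path = NULL) {
  out <- tibble::tibble(participant_id = records$participant_id)
  for (v in c("original", "wel", "wc", "wel_wc")) {
    cfg <- load_profile_config(v, path = profile_path)
    out[[paste0("mnps_", v)]] <- score_mnps(records, sugar_g, cfg)$total
  }
  out
}
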