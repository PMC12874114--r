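#' Spearman rank correlation
#'
#' The rank correlation used throughout the validity analysis: the Pearson
#' correlation of average-ranked values (ties receive average ranks). It is
#' symmetric and invariant to strictly increasing transforms of either
#' argument.
#'
#' @param x,y Numeric vectors of equal length >= 3; neither may be constant.
#' @return Correlation in \[-1, 1\].
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(rx, ry)
}

# decile rank with ties to the lower decile; boundaries are the inverse-ECDF
# order statistics x_(ceil(n k / 10)), computed in integer arithmetic so the
# cutpoints do not wobble with floating-point decile fractions
decile_rank <- function(x) {
  n <- length(x)
  if (n < 10L) {
    stop("decile mode needs at least 10 observations", call. = FALSE)
  }
  q <- sort(x)[ceiling(n * (1:9) / 10)]
  rowSums(outer(x, q, `>`))
}

#' Build the per-participant score panel
#'
#' Runs every scorer over a post-exclusion cohort: sugar imputation, the four
#' MNPS-OA variants, HEI-2015, NRF9.3 and the DQSJ.
#'
#' @param records Post-exclusion diet record tibble.
#' @param replication If `TRUE` (default) the indices are computed the way a
#'   brief-questionnaire study must compute them: HEI-2015 whole grains
#'   forced to 0 and DQSJ whole grains/nuts fixed at 0 points. `FALSE` uses
#'   all record fields.
#' @param sugar_pct Sugar percentage table, see [default_sugar_pct()].
#' @return A tibble with `participant_id`, `mnps_original`, `mnps_wel`,
#'   `mnps_wc`, `mnps_wel_wc`, `hei2015`, `nrf9_3`, `dqsj`.
#' @export
build_score_panel <- function(records, replication = TRUE,
                              sugar_pct = default_sugar_pct()) {
  records <- validate_diet_records(records)
  sugars <- impute_sugars(records, sugar_pct)
  profiles <- to_density_profile(records)
  added_pct <- sugar_pct$added_pct[match(records$sex, sugar_pct$sex)]

  panel <- score_all_variants(records, sugars$total_sugar_g)
  panel$hei2015 <- score_hei2015(profiles, added_pct,
                                 whole_grains_zero = replication)$total
  panel$nrf9_3 <- score_nrf93(records, sugars$added_sugar_g)
  zero_fixed <- if (replication) c("whole_grains", "nuts") else character()
  panel$dqsj <- score_dqsj(profiles, dqsj_config(zero_fixed))$total
  panel
}

#' Construct/convergent validity correlation report
#'
#' Computes the labelled Spearman matrices of the validity analysis:
#' construct validity (each model variant against the original), convergent
#' validity (each variant against HEI-2015, NRF9.3 and DQSJ), and a nutrient
#' panel correlating every energy-adjusted nutrient density (and the Na/K
#' ratio) with every score. `mode = "decile"` first coarsens every score to
#' its decile rank (ties to the lower decile) before correlating, a
#' sensitivity analysis for the differing score ranges; a subgroup filter
#' restricts to one sex or cohort first.
#'
#' @param panels Score panel from [build_score_panel()].
#' @param profiles Density profiles from [to_density_profile()], aligned on
#'   `participant_id` (also supplies `sex`/`cohort` for subgroups).
#' @param mode `"raw"` or `"decile"`.
#' @param subgroup Optional named length-1 character vector, e.g.
#'   `c(sex = "male")` or `c(cohort = "hatoyama")`.
#' @return A list of class `correlation_report`: `construct` (tibble
#'   `variant`, `r_with_original`), `convergent` (tibble `variant`, `index`,
#'   `r`), `nutrient_panel` (tibble `nutrient`, `score`, `r`), and `meta`.
#' @export
correlation_report <- function(panels, profiles, mode = c("raw", "decile"),
                               subgroup = NULL) {
  mode <- match.arg(mode)
  idx <- match(panels$participant_id, profiles$participant_id)
  if (anyNA(idx)) {
    stop("panels and profiles must align on participant_id", call. = FALSE)
  }
  profiles <- profiles[idx, ]
  if (!is.null(subgroup)) {
    var <- names(subgroup)
    if (!var %in% c("sex", "cohort")) {
      stop("subgroup must filter on sex or cohort", call. = FALSE)
    }
    keep <- profiles[[var]] == subgroup[[1]]
    panels <- panels[keep, ]
    profiles <- profiles[keep, ]
  }

  variants <- c("mnps_original", "mnps_wel", "mnps_wc", "mnps_wel_wc")
  indices <- intersect(c("hei2015", "nrf9_3", "dqsj"), names(panels))
  score_cols <- c(variants, indices)
  scores <- panels[score_cols]
  if (mode == "decile") {
    scores <- dplyr::mutate(scores,
                            dplyr::across(dplyr::everything(), decile_rank))
  }

  construct <- tibble::tibble(
    variant = variants,
    r_with_original = vapply(unname(variants), function(v) {
      spearman(scores$mnps_original, scores[[v]])
    }, numeric(1), USE.NAMES = FALSE)
  )
  convergent <- tidyr::expand_grid(variant = variants, index = indices)
  convergent$r <- mapply(function(v, i) spearman(scores[[v]], scores[[i]]),
                         convergent$variant, convergent$index)

  nutrient_cols <- setdiff(names(profiles),
                           c("participant_id", "sex", "cohort"))
  nutrient_panel <- tidyr::expand_grid(nutrient = nutrient_cols,
                                       score = score_cols)
  nutrient_panel$r <- mapply(
    function(nu, sc) spearman(profiles[[nu]], scores[[sc]]),
    nutrient_panel$nutrient, nutrient_panel$score
  )

  structure(
    list(construct = construct, convergent = convergent,
         nutrient_panel = nutrient_panel,
         meta = list(n = nrow(panels), mode = mode, subgroup = subgroup)),
    class = "correlation_report"
  )
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("Correlation report (n = ", x$meta$n, ", mode = ", x$meta$mode,
      if (!is.null(x$meta$subgroup)) {
        paste0(", ", names(x$meta$subgroup), " = ", x$meta$subgroup)
      } else "",
      ")\n", sep = "")
  cat("\nConstruct validity (Spearman r with original model):\n")
  print(x$construct)
  cat("\nConvergent validity:\n")
  print(tidyr::pivot_wider(x$convergent, names_from = "index",
                           values_from = "r"))
  invisible(x)
}

#' Cohort descriptives with two-group tests
#'
#' Continuous variables are summarised as median (Q1, Q3) per group with a
#' two-sided Mann–Whitney (Wilcoxon rank-sum) p-value; categorical variables
#' as n (%) per level with a chi-square test, switching to Fisher's exact
#' test when any expected cell count falls below 5. P-values are unadjusted.
#'
#' @param records Diet record tibble.
#' @param panels Matching score panel (scores are summarised as continuous
#'   rows); may be `NULL`.
#' @param group_var Grouping column, default `"cohort"`; must have exactly
#'   two levels present.
#' @return A tibble with `variable`, one summary column per group, `p_value`
#'   and `test`.
#' @export
descriptive_table <- function(records, panels = NULL, group_var = "cohort") {
  g <- factor(records[[group_var]])
  if (nlevels(g) != 2L) {
    stop("descriptive_table needs exactly two groups in '", group_var, "'",
         call. = FALSE)
  }
  lv <- levels(g)
  cont <- tibble::tibble(name = c("age", "energy"),
                         value = list(records$age, records$energy))
  if (!is.null(panels)) {
    for (col in setdiff(names(panels), "participant_id")) {
      cont <- dplyr::bind_rows(
        cont, tibble::tibble(name = col, value = list(panels[[col]]))
      )
    }
  }
  summarise_cont <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    sprintf("%.1f (%.1f, %.1f)", q[2], q[1], q[3])
  }
  rows <- lapply(seq_len(nrow(cont)), function(i) {
    x <- cont$value[[i]]
    p <- suppressWarnings(
      stats::wilcox.test(x[g == lv[1]], x[g == lv[2]])$p.value)
    out <- tibble::tibble(variable = cont$name[i],
                          a = summarise_cont(x[g == lv[1]]),
                          b = summarise_cont(x[g == lv[2]]),
                          p_value = p, test = "wilcoxon")
    names(out)[2:3] <- lv
    out
  })
  # categorical: sex; the exact test replaces chi-square under sparse cells
  tab <- table(records$sex, g)
  if (nrow(tab) < 2L) {
    p <- NA_real_
    test <- "none (single level)"
  } else {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      p <- stats::fisher.test(tab)$p.value
      test <- "fisher"
    } else {
      p <- stats::chisq.test(tab, correct = FALSE)$p.value
      test <- "chi-square"
    }
  }
  pct <- function(col) {
    paste(sprintf("%s %d (%.1f%%)", rownames(tab), tab[, col],
                  100 * tab[, col] / sum(tab[, col])), collapse = "; ")
  }
  sex_row <- tibble::tibble(variable = "sex", a = pct(1), b = pct(2),
                            p_value = p, test = test)
  names(sex_row)[2:3] <- lv
  dplyr::bind_rows(sex_row, rows)
}

#' Run the full scoring and validation pipeline
#'
#' Simulate (or load) a cohort, apply eligibility exclusions, score all
#' indices, and write the analysis artifacts to `out_dir`: the score table
#' (`scores.csv`), cohort descriptives (`descriptives.csv`), construct and
#' convergent validity (`construct.csv`, `convergent.csv`), the nutrient
#' correlation panel (`nutrient_panel.csv`), and a run log
#' (`run_log.txt`) recording the seed, exclusion counts and a config hash.
#' Deterministic given the seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param n Cohort size to simulate; ignored when `cohort` is given.
#' @param seed Integer seed for simulation.
#' @param cohort Optional pre-built diet record tibble; when supplied, the
#'   simulation stage is skipped.
#' @param spec Optional [cohort_spec()] overriding `n`/`seed`.
#' @param energy_low,energy_high Energy plausibility window (kcal/d).
#' @param replication Passed to [build_score_panel()].
#' @return Invisibly, a list with `panel`, `profiles`, `report`,
#'   `descriptives`, `exclusions`.
#' @export
run_pipeline <- function(out_dir, n = 1130, seed = 1, cohort = NULL,
                         spec = NULL, energy_low = 600, energy_high = 4000,
                         replication = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  result <- tryCatch({
    if (is.null(cohort)) {
      spec <- spec %||% default_spec(n, seed, n_no_consent = 12L,
                                     n_energy_outliers = 16L)
      cohort <- generate_cohort(spec)
    }
    stage <- "preprocess"
    excl <- apply_exclusions(cohort, energy_low, energy_high)
    stage <- "score"
    panel <- build_score_panel(excl$kept, replication = replication)
    profiles <- to_density_profile(excl$kept)
    stage <- "validate"
    report <- correlation_report(panel, profiles, mode = "raw")
    descr <- descriptive_table(excl$kept, panel)
    stage <- "write"
    write_score_table(panel, file.path(out_dir, "scores.csv"))
    readr::write_csv(descr, file.path(out_dir, "descriptives.csv"))
    readr::write_csv(report$construct, file.path(out_dir, "construct.csv"))
    readr::write_csv(report$convergent, file.path(out_dir, "convergent.csv"))
    readr::write_csv(report$nutrient_panel,
                     file.path(out_dir, "nutrient_panel.csv"))
    writeLines(c(
      sprintf("seed: %s", if (is.null(spec)) "external cohort" else spec$seed),
      sprintf("n_input: %d", nrow(cohort)),
      sprintf("n_kept: %d", nrow(excl$kept)),
      sprintf("n_excluded_consent: %d", nrow(excl$excluded_consent)),
      sprintf("n_excluded_energy: %d", nrow(excl$excluded_energy)),
      sprintf("config_hash: %s", rlang::hash(list(spec, energy_low,
                                                  energy_high, replication)))
    ), file.path(out_dir, "run_log.txt"))
    list(panel = panel, profiles = profiles, report = report,
         descriptives = descr, exclusions = excl)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
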