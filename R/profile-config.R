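#' Load a scoring profile for one MNPS-OA model variant
#'
#' The MNPS-OA scores a diet from nine items to encourage (protein, dietary
#' fiber, vitamin D, calcium, fruits, vegetables, nuts, legumes, dairy) and
#' up to three items to limit (energy, sugar, sodium). Each encourage item
#' has a reference daily value (RDV) and a creditable cap expressed as a
#' fraction of the RDV; each limit item has an RDV against which the
#' deduction is scaled. The four variants are:
#' \describe{
#'   \item{original}{energy, sugar and sodium limits; population-calibrated
#'     caps on calcium, fruits, vegetables, legumes and dairy.}
#'   \item{wel}{without the energy limit; caps as in original.}
#'   \item{wc}{without nutrient caps (points accrue up to the full RDV);
#'     energy limit retained.}
#'   \item{wel_wc}{without either.}
#' }
#' Profiles are shipped as an editable YAML document (see
#' `system.file("extdata", "mnps_oa_profiles.yaml", package = "mnpsdiet")`)
#' because cut-offs of this kind must be recalibrated for other target
#' populations; the file is validated on load.
#'
#' @param variant One of `"original"`, `"wel"`, `"wc"`, `"wel_wc"`.
#' @param path Path to a profiles YAML; defaults to the shipped table.
#' @return A list of class `mnps_profile` with elements `variant`,
#'   `limit_items` (tibble: `name`, `rdv`) and `encourage_items`
#'   (tibble: `name`, `rdv`, `cap_fraction`).
#' @export
#' @examples
#' cfg <- load_profile_config("original")
#' cfg$encourage_items
load_profile_config <- function(variant = c("original", "wel", "wc", "wel_wc"),
                                path = NULL) {
  variant <- match.arg(variant)
  path <- path %||% system.file("extdata", "mnps_oa_profiles.yaml",
                                package = "mnpsdiet", mustWork = TRUE)
  all_cfg <- yaml::read_yaml(path)
  if (is.null(all_cfg[[variant]])) {
    stop("profile file has no entry for variant '", variant, "'",
         call. = FALSE)
  }
  raw <- all_cfg[[variant]]
  limit <- tibble::tibble(
    name = names(raw$limit_items),
    rdv = unname(vapply(raw$limit_items, function(x) as.numeric(x$rdv),
                        numeric(1)))
  )
  enc <- tibble::tibble(
    name = names(raw$encourage_items),
    rdv = unname(vapply(raw$encourage_items, function(x) as.numeric(x$rdv),
                        numeric(1))),
    cap_fraction = unname(vapply(raw$encourage_items,
                                 function(x) as.numeric(x$cap_amount) /
                                   as.numeric(x$rdv),
                                 numeric(1)))
  )
  cfg <- structure(
    list(variant = variant, limit_items = limit, encourage_items = enc),
    class = "mnps_profile"
  )
  validate_profile_config(cfg)
  cfg
}

validate_profile_config <- function(cfg) {
  enc <- cfg$encourage_items
  lim <- cfg$limit_items
  if (nrow(enc) != 9L) {
    stop("profile must have exactly 9 encourage items", call. = FALSE)
  }
  if (!nrow(lim) %in% c(2L, 3L)) {
    stop("profile must have 2 or 3 limit items", call. = FALSE)
  }
  if (!all(c("sugar", "sodium") %in% lim$name)) {
    stop("sugar and sodium must be limit items in every variant",
         call. = FALSE)
  }
  if (cfg$variant %in% c("wel", "wel_wc") && "energy" %in% lim$name) {
    stop("without-energy-limit variants must not list energy as a limit item",
         call. = FALSE)
  }
  if (any(enc$rdv <= 0) || any(lim$rdv <= 0)) {
    stop("all RDVs must be > 0", call. = FALSE)
  }
  if (any(enc$cap_fraction <= 0 | enc$cap_fraction > 1)) {
    stop("cap fractions must lie in (0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.mnps_profile <- function(x, ...) {
  cat("MNPS-OA scoring profile, variant '", x$variant, "'\n", sep = "")
  cat("Limit items:\n")
  print(x$limit_items)
  cat("Encourage items:\n")
  print(x$encourage_items)
  invisible(x)
}
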