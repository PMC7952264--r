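#' Canonical Exposure Factors Handbook age groups
#'
#' The eleven age groups used for per-age-group average daily dose (ADD)
#' estimation: four sub-year infant groups, six further childhood groups and
#' one adult group, jointly covering birth to <70 years with no gaps or
#' overlaps. Ages are half-open intervals `[start_age, end_age)` in years;
#' sub-year bounds are exact month fractions (1/12, 3/12, ...).
#'
#' @return A tibble with columns `age_group` (canonical label), `start_age`,
#'   `end_age` and `span_years` (all in years), in chronological order.
#' @examples
#' age_group_roster()
#' @export
age_group_roster <- function() {
  x <- tibble::tribble(
    ~age_group,     ~start_age, ~end_age,
    "birth_to_1mo", 0,          1 / 12,
    "1_3mo",        1 / 12,     3 / 12,
    "3_6mo",        3 / 12,     6 / 12,
    "6_12mo",       6 / 12,     1,
    "1_2y",         1,          2,
    "2_3y",         2,          3,
    "3_6y",         3,          6,
    "6_11y",        6,          11,
    "11_16y",       11,         16,
    "16_21y",       16,         21,
    "21_70y",       21,         70
  )
  dplyr::mutate(x, span_years = .data$end_age - .data$start_age)
}

#' Canonical oral exposure media
#'
#' The ten ingestion media considered for aggregate oral exposure, with the
#' unit class of their intake rate and the unit their concentrations are
#' expressed in. Soil and dust intake is a mass rate (mg/day, not
#' body-weight normalised); water and breastmilk intake is a per-kg volume
#' rate (mL/kg-day); the six food groups are per-kg mass rates (g/kg-day).
#'
#' @return A tibble with columns `medium`, `intake_unit_class` (one of
#'   `"mass_per_day"`, `"volume_per_kg_day"`, `"mass_per_kg_day"`) and
#'   `concentration_unit` (`"mg/g"` or `"mg/mL"`), in canonical stacking
#'   order.
#' @examples
#' media_roster()
#' @export
media_roster <- function() {
  tibble::tribble(
    ~medium,      ~intake_unit_class,  ~concentration_unit,
    "soil",       "mass_per_day",      "mg/g",
    "dust",       "mass_per_day",      "mg/g",
    "water",      "volume_per_kg_day", "mg/mL",
    "breastmilk", "volume_per_kg_day", "mg/mL",
    "dairy",      "mass_per_kg_day",   "mg/g",
    "meat",       "mass_per_kg_day",   "mg/g",
    "fish",       "mass_per_kg_day",   "mg/g",
    "vegetables", "mass_per_kg_day",   "mg/g",
    "fruit",      "mass_per_kg_day",   "mg/g",
    "grains",     "mass_per_kg_day",   "mg/g"
  )
}

#' Canonical lifestage mapping
#'
#' Maps the eleven age groups onto seven lifestages: the four sub-year
#' groups form the young-infant lifestage (1 year total), the 1--<2 and
#' 2--<3 year groups form the infant lifestage (2 years), and the remaining
#' five groups map one-to-one (young child 3 y, child 5 y, young youth 5 y,
#' youth 5 y, adult 49 y). Lifestage durations sum to the 70-year lifespan.
#'
#' @return A tibble with one row per (lifestage, member age group) pair:
#'   columns `lifestage`, `age_group`, `span_years` (member weight) and
#'   `duration_years` (total years in the lifestage).
#' @examples
#' lifestage_map()
#' @export
lifestage_map <- function() {
  m <- tibble::tribble(
    ~lifestage,     ~age_group,
    "young_infant", "birth_to_1mo",
    "young_infant", "1_3mo",
    "young_infant", "3_6mo",
    "young_infant", "6_12mo",
    "infant",       "1_2y",
    "infant",       "2_3y",
    "young_child",  "3_6y",
    "child",        "6_11y",
    "young_youth",  "11_16y",
    "youth",        "16_21y",
    "adult",        "21_70y"
  )
  m <- dplyr::left_join(m, age_group_roster()[, c("age_group", "span_years")],
    by = "age_group"
  )
  dplyr::mutate(m,
    duration_years = stats::ave(.data$span_years, .data$lifestage, FUN = sum)
  )
}

#' @rdname lifestage_map
#' @details `lifestage_levels()` returns the chronological ordering of the
#'   seven lifestage labels; `aggregate_levels()` the three aggregate rows
#'   (childhood = birth--<21 y, adult_agg = the adult lifestage, lifetime =
#'   birth--<70 y) appended after them in tables and graphs.
#' @export
lifestage_levels <- function() {
  c(
    "young_infant", "infant", "young_child", "child",
    "young_youth", "youth", "adult"
  )
}

#' @rdname lifestage_map
#' @export
aggregate_levels <- function() {
  c("childhood", "adult_agg", "lifetime")
}

# internal: validate that a user mapping partitions the roster
check_mapping <- function(mapping, age_groups = age_group_roster()$age_group) {
  stopifnot(is.data.frame(mapping), all(c("lifestage", "age_group", "span_years") %in% names(mapping)))
  dup <- mapping$age_group[duplicated(mapping$age_group)]
  if (length(dup) > 0) {
    stop("lifestage mapping assigns age group(s) more than once: ",
      paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  missing <- setdiff(age_groups, mapping$age_group)
  if (length(missing) > 0) {
    stop("lifestage mapping omits age group(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  extra <- setdiff(mapping$age_group, age_groups)
  if (length(extra) > 0) {
    stop("lifestage mapping names unknown age group(s): ",
      paste(extra, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(mapping)
}
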