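#' Regroup per-age-group doses into lifestages
#'
#' Converts the eleven-age-group ADD grid into the seven lifestages by
#' time-weighted averaging: for each medium,
#' \deqn{ADD_j = \frac{\sum_i ADD_i \times Y_i}{\sum_i Y_i}}
#' over the member age groups of lifestage \eqn{j}, where \eqn{Y_i} is the
#' member's length in years (sub-year members carry exact month fractions
#' 1/12, 2/12, 3/12, 6/12). Lifetime average daily doses are then derived as
#' \deqn{LADD_j = ADD_j \times Y_j / \mathrm{Lifespan}}
#' with a default 70-year lifespan, and three time-weighted aggregate rows
#' are appended: childhood (birth--<21 y), adult, and lifetime
#' (birth--<70 y).
#'
#' @param add_table an `add_tbl` from [build_add_table()] or
#'   [import_add_table()].
#' @param mapping a lifestage mapping partitioning the table's age groups;
#'   defaults to the canonical seven-lifestage scheme ([lifestage_map()]).
#' @param lifespan_years lifespan used for LADD weighting (default 70).
#' @return A `lifestage_dose` object: a list with `$doses` (tibble with
#'   columns `row_type` = `"lifestage"`/`"aggregate"`, `lifestage`,
#'   `medium`, `years`, `add`, `ladd`), `$chemical`, `$lifespan_years` and
#'   `$mapping`. Use [tidy()][generics::tidy], [glance()][generics::glance]
#'   or [autoplot()][ggplot2::autoplot] on it.
#' @examples
#' add <- build_add_table(load_fixture("dehp"), default_exposure_factors(), "DEHP")
#' ls <- regroup_lifestages(add)
#' glance(ls)
#' @export
regroup_lifestages <- function(add_table, mapping = lifestage_map(),
                               lifespan_years = 70) {
  stopifnot(is.data.frame(add_table), lifespan_years > 0)
  check_mapping(mapping, unique(add_table$age_group))
  stages <- dplyr::inner_join(
    add_table[, c("medium", "age_group", "add")],
    mapping[, c("lifestage", "age_group", "span_years")],
    by = "age_group"
  )
  stages <- dplyr::summarise(
    dplyr::group_by(stages, .data$lifestage, .data$medium),
    years = sum(.data$span_years),
    add = sum(.data$add * .data$span_years) / sum(.data$span_years),
    .groups = "drop"
  )
  stages$row_type <- "lifestage"
  agg <- compute_aggregates(add_table, mapping)
  doses <- dplyr::bind_rows(stages, agg)
  doses <- dplyr::mutate(doses,
    lifestage = factor(.data$lifestage,
      levels = c(
        intersect(lifestage_levels(), mapping$lifestage),
        setdiff(unique(mapping$lifestage), lifestage_levels()),
        aggregate_levels()
      )
    ),
    medium = factor(.data$medium, levels = media_roster()$medium)
  )
  doses <- dplyr::arrange(doses, .data$lifestage, .data$medium)
  doses <- doses[, c("row_type", "lifestage", "medium", "years", "add")]
  out <- structure(
    list(
      doses = doses,
      chemical = attr(add_table, "chemical") %||% "chemical",
      lifespan_years = lifespan_years,
      mapping = mapping
    ),
    class = "lifestage_dose"
  )
  compute_ladd(out)
}

#' Fill in lifetime average daily doses
#'
#' Computes `ladd = add * years / lifespan_years` for every row of a
#' `lifestage_dose` object (aggregate rows use their own durations: 21
#' childhood years, 49 adult years, the full lifespan for the lifetime
#' row, so the lifetime LADD equals its ADD).
#'
#' @param x a `lifestage_dose` object.
#' @param lifespan_years optional override of the stored lifespan.
#' @return `x` with the `ladd` column (re)computed.
#' @export
compute_ladd <- function(x, lifespan_years = x$lifespan_years) {
  stopifnot(inherits(x, "lifestage_dose"), lifespan_years > 0)
  x$lifespan_years <- lifespan_years
  x$doses$ladd <- x$doses$add * x$doses$years / lifespan_years
  x
}

#' Time-weighted aggregate dose rows
#'
#' Builds the childhood (birth--<21 y), adult and lifetime (birth--<70 y)
#' ADD rows from the per-age-group grid. Childhood and lifetime are
#' time-weighted means over their member age groups -- the same weighting
#' that defines the lifestage ADDs, so the lifetime row per medium equals
#' \eqn{\sum_j ADD_j Y_j / 70}, i.e. the sum of the lifestage LADDs.
#'
#' @inheritParams regroup_lifestages
#' @return A tibble of aggregate rows (`row_type = "aggregate"`, lifestages
#'   `childhood`, `adult_agg`, `lifetime`) with `years` and `add` columns.
#' @export
compute_aggregates <- function(add_table, mapping = lifestage_map()) {
  check_mapping(mapping, unique(add_table$age_group))
  x <- dplyr::inner_join(
    add_table[, c("medium", "age_group", "add")],
    mapping[, c("age_group", "span_years", "lifestage")],
    by = "age_group"
  )
  adult_groups <- mapping$age_group[mapping$lifestage == "adult"]
  x$section <- ifelse(x$age_group %in% adult_groups, "adult_agg", "childhood")
  one <- function(d, label) {
    out <- dplyr::summarise(
      dplyr::group_by(d, .data$medium),
      years = sum(.data$span_years),
      add = sum(.data$add * .data$span_years) / sum(.data$span_years),
      .groups = "drop"
    )
    out$lifestage <- label
    out
  }
  agg <- dplyr::bind_rows(
    one(x[x$section == "childhood", ], "childhood"),
    one(x[x$section == "adult_agg", ], "adult_agg"),
    one(x, "lifetime")
  )
  agg$row_type <- "aggregate"
  agg[, c("row_type", "lifestage", "medium", "years", "add")]
}

#' Percent media contributions within each lifestage
#'
#' Converts lifestage ADDs to percent contributions of each medium within
#' each lifestage (and aggregate row):
#' \deqn{\%_{j,m} = 100 \times ADD_{j,m} / \sum_m ADD_{j,m}.}
#' Rows whose total ADD is zero are returned as all-zero and flagged
#' (`empty = TRUE`) rather than NaN, so downstream plotting never divides
#' by zero.
#'
#' @param x a `lifestage_dose` object.
#' @return A tibble with columns `row_type`, `lifestage`, `medium`,
#'   `percent` and `empty`.
#' @export
percent_contributions <- function(x) {
  stopifnot(inherits(x, "lifestage_dose"))
  out <- dplyr::mutate(
    dplyr::group_by(x$doses, .data$row_type, .data$lifestage),
    total = sum(.data$add),
    empty = .data$total == 0,
    percent = ifelse(.data$empty, 0, 100 * .data$add / .data$total)
  )
  out <- dplyr::ungroup(out)
  out[, c("row_type", "lifestage", "medium", "percent", "empty")]
}

#' @export
print.lifestage_dose <- function(x, ...) {
  cat(
    "Lifestage dose table for", x$chemical,
    sprintf("(lifespan %g y)\n", x$lifespan_years)
  )
  print(x$doses, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a lifestage dose table
#'
#' @param x a `lifestage_dose` object.
#' @param include_aggregates keep the childhood/adult/lifetime rows
#'   (default `TRUE`).
#' @param ... unused.
#' @return A tibble with one row per (lifestage, medium): `row_type`,
#'   `lifestage`, `medium`, `years`, `add`, `ladd`, `percent`, `empty`.
#' @method tidy lifestage_dose
#' @export
tidy.lifestage_dose <- function(x, include_aggregates = TRUE, ...) {
  out <- dplyr::left_join(
    x$doses, percent_contributions(x),
    by = c("row_type", "lifestage", "medium")
  )
  if (!include_aggregates) out <- out[out$row_type == "lifestage", ]
  tibble::as_tibble(out)
}

#' One-row summary of a lifestage dose table
#'
#' @param x a `lifestage_dose` object.
#' @param ... unused.
#' @return A one-row tibble: chemical, lifespan, number of lifestages and
#'   media with nonzero dose, lifetime aggregate ADD summed over media, the
#'   lifestage and the medium with the largest ADD contribution.
#' @method glance lifestage_dose
#' @export
glance.lifestage_dose <- function(x, ...) {
  d <- x$doses[x$doses$row_type == "lifestage", ]
  by_stage <- dplyr::summarise(dplyr::group_by(d, .data$lifestage),
    add = sum(.data$add), .groups = "drop"
  )
  by_medium <- dplyr::summarise(dplyr::group_by(d, .data$medium),
    ladd = sum(.data$ladd), .groups = "drop"
  )
  lifetime <- x$doses[x$doses$row_type == "aggregate" &
    x$doses$lifestage == "lifetime", ]
  tibble::tibble(
    chemical = x$chemical,
    lifespan_years = x$lifespan_years,
    n_lifestages = dplyr::n_distinct(d$lifestage),
    n_media_nonzero = sum(by_medium$ladd > 0),
    lifetime_add = sum(lifetime$add),
    peak_lifestage = as.character(by_stage$lifestage[which.max(by_stage$add)]),
    top_medium = as.character(by_medium$medium[which.max(by_medium$ladd)])
  )
}
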