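#' Average daily dose from one medium
#'
#' Evaluates the deterministic oral dose equation
#' \deqn{ADD = \frac{C \times IR \times EF \times ED}{AT \times BW}}
#' where `C` is the mean concentration in the medium (mg/g for solids and
#' foods, mg/mL for liquids), `IR` the intake rate, `EF` the exposure
#' frequency (days/year), `ED` the exposure duration (years), `AT` the
#' averaging time (days) and `BW` the body weight (kg).
#'
#' Unit handling depends on the intake-rate unit class:
#' \itemize{
#'   \item `mass_per_day` (soil, dust; IR in mg/day): IR is converted to
#'     g/day (factor 1e-3) so that C in mg/g yields mg/day, and the result
#'     is divided by body weight.
#'   \item `volume_per_kg_day` (water, breastmilk; mL/kg-day) and
#'     `mass_per_kg_day` (foods; g/kg-day): the intake rate is already
#'     body-weight normalised, so the BW divisor is omitted.
#' }
#' Under the chronic central-tendency scenario (EF = 365, AT = ED × 365)
#' the time terms cancel and the dose reduces to `C × IR` (divided by BW
#' for soil and dust).
#'
#' @param concentration mean concentration `C`, in the medium's unit.
#' @param intake_rate intake rate `IR`, in the class's unit.
#' @param intake_unit_class one of `"mass_per_day"`, `"volume_per_kg_day"`,
#'   `"mass_per_kg_day"` (vectorised, recycled).
#' @param exposure_frequency days per year (default 365).
#' @param exposure_duration years.
#' @param averaging_time days; must be > 0.
#' @param body_weight kg; must be > 0.
#' @return Dose in mg/kg-day (numeric, same length as the inputs).
#' @examples
#' # soil: 0.341 mg/g x 50 mg/day / 15 kg (chronic scenario)
#' add_dose(0.341, 50, "mass_per_day",
#'   exposure_duration = 3, averaging_time = 3 * 365, body_weight = 15
#' )
#' @export
add_dose <- function(concentration, intake_rate, intake_unit_class,
                     exposure_frequency = 365, exposure_duration = 1,
                     averaging_time = exposure_duration * 365,
                     body_weight = 1) {
  classes <- c("mass_per_day", "volume_per_kg_day", "mass_per_kg_day")
  if (!all(intake_unit_class %in% classes)) {
    stop("unknown intake_unit_class: ",
      paste(setdiff(unique(intake_unit_class), classes), collapse = ", "),
      call. = FALSE
    )
  }
  if (any(averaging_time <= 0)) {
    stop("averaging_time must be > 0 (degenerate averaging window)", call. = FALSE)
  }
  if (any(body_weight <= 0)) {
    stop("body_weight must be > 0", call. = FALSE)
  }
  if (any(concentration < 0) || any(intake_rate < 0) ||
    any(exposure_frequency < 0) || any(exposure_duration < 0)) {
    stop("concentration, intake_rate, exposure_frequency and exposure_duration must be >= 0",
      call. = FALSE
    )
  }
  mass_per_day <- intake_unit_class == "mass_per_day"
  # mg/day -> g/day so C [mg/g] x IR yields mg/day; per-kg classes skip BW
  ir <- ifelse(mass_per_day, intake_rate * 1e-3, intake_rate)
  bw <- ifelse(mass_per_day, body_weight, 1)
  dose <- concentration * ir * exposure_frequency * exposure_duration /
    (averaging_time * bw)
  stopifnot(all(is.finite(dose)), all(dose >= 0))
  dose
}

#' Per-age-group ADD for matched concentration and factor rows
#'
#' Joins a table of per-medium mean concentrations to a table of exposure
#' factors (one row per medium and age group) and evaluates [add_dose()]
#' row-wise. Concentration units must match the medium's canonical unit.
#'
#' @param factors tibble with columns `medium`, `age_group`, `intake_rate`,
#'   `intake_unit`, `exposure_frequency`, `exposure_duration`,
#'   `averaging_time`, `body_weight`.
#' @param concentrations tibble with columns `medium`, `mean` and
#'   optionally `unit`.
#' @return The factor tibble with the concentration and an `add` column
#'   (mg/kg-day) appended.
#' @export
compute_add <- function(factors, concentrations) {
  roster <- media_roster()
  bad <- setdiff(unique(c(factors$medium, concentrations$medium)), roster$medium)
  if (length(bad) > 0) {
    stop("unknown medium: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if ("unit" %in% names(concentrations)) {
    chk <- dplyr::inner_join(concentrations, roster, by = "medium")
    off <- chk[!is.na(chk$unit) & chk$unit != chk$concentration_unit, ]
    if (nrow(off) > 0) {
      stop(
        "concentration unit mismatch for ", off$medium[1], ": got '",
        off$unit[1], "', medium requires '", off$concentration_unit[1], "'",
        call. = FALSE
      )
    }
  }
  x <- dplyr::inner_join(
    factors,
    concentrations[, c("medium", "mean")],
    by = "medium"
  )
  x <- dplyr::left_join(x, roster[, c("medium", "intake_unit_class")], by = "medium")
  if ("intake_unit" %in% names(x)) {
    want <- c(
      mass_per_day = "mg/day", volume_per_kg_day = "mL/kg-day",
      mass_per_kg_day = "g/kg-day"
    )
    off <- x[x$intake_unit != want[x$intake_unit_class], ]
    if (nrow(off) > 0) {
      stop(
        "intake unit mismatch for ", off$medium[1], " / ", off$age_group[1],
        ": got '", off$intake_unit[1], "', expected '",
        want[[off$intake_unit_class[1]]], "'",
        call. = FALSE
      )
    }
  }
  dplyr::mutate(x, add = add_dose(
    .data$mean, .data$intake_rate, .data$intake_unit_class,
    .data$exposure_frequency, .data$exposure_duration,
    .data$averaging_time, .data$body_weight
  ))
}

#' Assemble the eleven-age-group by ten-media ADD table
#'
#' Builds the full dose grid for one chemical: one [add_dose()] evaluation
#' per (age group, medium) pair that has a concentration, and explicit
#' zero-filled columns (flagged `"absent"`) for canonical media with no
#' concentration, so grids remain comparable across chemicals.
#'
#' @param concentrations per-medium mean concentrations (see
#'   [compute_add()]); media not listed, or listed with `absent = TRUE`,
#'   become zero columns.
#' @param factors exposure-factor table covering the eleven canonical age
#'   groups for every medium with a concentration (see
#'   [default_exposure_factors()]).
#' @param chemical chemical name recorded on the table.
#' @return An `add_tbl`: a tibble with columns `medium`, `age_group`, `add`
#'   (mg/kg-day) and `provenance` (`"computed"` or `"absent"`), 110 rows,
#'   with the chemical name stored as an attribute.
#' @examples
#' add <- build_add_table(
#'   load_fixture("dehp"), default_exposure_factors(),
#'   chemical = "DEHP"
#' )
#' @export
build_add_table <- function(concentrations, factors, chemical = "chemical") {
  roster <- media_roster()
  ages <- age_group_roster()
  if ("absent" %in% names(concentrations)) {
    concentrations <- concentrations[!isTRUE_vec(concentrations$absent), ]
  }
  bad <- setdiff(concentrations$medium, roster$medium)
  if (length(bad) > 0) {
    stop("unknown medium: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(concentrations$medium)) {
    stop("duplicate concentration rows for a medium", call. = FALSE)
  }
  dup <- duplicated(factors[, c("medium", "age_group")])
  if (any(dup)) {
    stop(
      "duplicate exposure-factor rows for ",
      paste(factors$medium[dup], factors$age_group[dup], sep = "/", collapse = ", "),
      call. = FALSE
    )
  }
  present <- concentrations$medium
  need <- tidyr::expand_grid(medium = present, age_group = ages$age_group)
  have <- dplyr::semi_join(need, factors, by = c("medium", "age_group"))
  if (nrow(have) < nrow(need)) {
    miss <- dplyr::anti_join(need, factors, by = c("medium", "age_group"))
    stop(
      "exposure factors missing for ",
      paste(miss$medium, miss$age_group, sep = "/", collapse = ", "),
      call. = FALSE
    )
  }
  computed <- compute_add(
    dplyr::semi_join(factors, concentrations, by = "medium"),
    concentrations
  )
  grid <- tidyr::expand_grid(medium = roster$medium, age_group = ages$age_group)
  grid <- dplyr::left_join(grid,
    computed[, c("medium", "age_group", "add")],
    by = c("medium", "age_group")
  )
  grid <- dplyr::mutate(grid,
    provenance = ifelse(is.na(.data$add), "absent", "computed"),
    add = ifelse(is.na(.data$add), 0, .data$add)
  )
  new_add_tbl(grid, chemical)
}

isTRUE_vec <- function(x) !is.na(x) & x

new_add_tbl <- function(grid, chemical) {
  grid <- dplyr::arrange(
    grid,
    factor(.data$medium, levels = media_roster()$medium),
    factor(.data$age_group, levels = age_group_roster()$age_group)
  )
  stopifnot(all(grid$add >= 0))
  out <- tibble::new_tibble(grid, chemical = chemical,
    class = c("add_tbl", "tbl_df", "tbl")
  )
  out
}

#' @export
print.add_tbl <- function(x, ...) {
  cat("ADD table (mg/kg-day) for", attr(x, "chemical") %||% "?", "\n")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# CSV writer that round-trips doubles exactly (17 significant digits)
write_csv_full <- function(df, path) {
  num <- vapply(df, function(x) is.numeric(x) && !is.integer(x), logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  })
  readr::write_csv(df, path, na = "NA")
  invisible(path)
}

#' Read and write ADD tables in the media-by-age-group grid layout
#'
#' The interchange layout mirrors the per-age-group export of scenario
#' tools: a CSV whose first column is `medium` (the ten canonical names)
#' and whose remaining eleven columns are the canonical age-group labels,
#' values in mg/kg-day. `import_add_table()` validates headers and cells
#' (rejecting unknown age-group columns, non-numeric or negative cells with
#' their coordinates) and zero-fills media rows missing from the file with
#' a warning. `export_add_table()` writes the same layout, so the pair
#' round-trips.
#'
#' @param path CSV file path.
#' @param chemical chemical name to record.
#' @return `import_add_table()`: an `add_tbl` (see [build_add_table()]).
#' @export
import_add_table <- function(path, chemical = "chemical") {
  wide <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (names(wide)[1] != "medium") {
    stop("malformed header: first column must be 'medium', got '", names(wide)[1], "'",
      call. = FALSE
    )
  }
  ages <- age_group_roster()$age_group
  bad_cols <- setdiff(names(wide)[-1], ages)
  if (length(bad_cols) > 0) {
    stop("unknown age-group column(s): ", paste(bad_cols, collapse = ", "),
      call. = FALSE
    )
  }
  miss_cols <- setdiff(ages, names(wide))
  if (length(miss_cols) > 0) {
    stop("missing age-group column(s): ", paste(miss_cols, collapse = ", "),
      call. = FALSE
    )
  }
  bad_media <- setdiff(wide$medium, media_roster()$medium)
  if (length(bad_media) > 0) {
    stop("unknown medium row(s): ", paste(bad_media, collapse = ", "), call. = FALSE)
  }
  long <- tidyr::pivot_longer(wide, -"medium",
    names_to = "age_group", values_to = "raw"
  )
  long$add <- suppressWarnings(as.numeric(long$raw))
  bad <- which(is.na(long$add))
  if (length(bad) > 0) {
    stop(
      "non-numeric ADD cell at medium '", long$medium[bad[1]],
      "', age group '", long$age_group[bad[1]], "': '", long$raw[bad[1]], "'",
      call. = FALSE
    )
  }
  neg <- which(long$add < 0)
  if (length(neg) > 0) {
    stop(
      "negative ADD cell at medium '", long$medium[neg[1]],
      "', age group '", long$age_group[neg[1]], "': ", long$add[neg[1]],
      call. = FALSE
    )
  }
  missing_media <- setdiff(media_roster()$medium, wide$medium)
  if (length(missing_media) > 0) {
    warning("medium row(s) missing, zero-filled: ",
      paste(missing_media, collapse = ", "),
      call. = FALSE
    )
  }
  grid <- tidyr::expand_grid(
    medium = media_roster()$medium,
    age_group = age_group_roster()$age_group
  )
  grid <- dplyr::left_join(grid, long[, c("medium", "age_group", "add")],
    by = c("medium", "age_group")
  )
  grid <- dplyr::mutate(grid,
    provenance = ifelse(is.na(.data$add), "absent",
      ifelse(.data$medium %in% missing_media, "absent", "imported")
    ),
    add = ifelse(is.na(.data$add), 0, .data$add)
  )
  new_add_tbl(grid, chemical)
}

#' @rdname import_add_table
#' @param x an `add_tbl`.
#' @export
export_add_table <- function(x, path) {
  wide <- tidyr::pivot_wider(
    x[, c("medium", "age_group", "add")],
    names_from = "age_group", values_from = "add"
  )
  wide <- wide[match(media_roster()$medium, wide$medium), ]
  write_csv_full(wide, path)
  invisible(path)
}
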