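# shared fixtures built in code

# wide ADD grid (media x age groups) written to CSV and re-imported, so the
# import path is exercised and arbitrary grids are easy to make
write_grid_csv <- function(values, path = tempfile(fileext = ".csv"),
                           media = media_roster()$medium,
                           ages = age_group_roster()$age_group) {
  stopifnot(length(values) == length(media) * length(ages))
  wide <- cbind(
    data.frame(medium = media),
    matrix(values,
      nrow = length(media), byrow = TRUE,
      dimnames = list(NULL, ages)
    )
  )
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  path
}

random_add_tbl <- function(seed, chemical = "synthetic", max = 1) {
  withr::with_seed(seed, {
    vals <- stats::runif(110, 0, max)
  })
  import_add_table(write_grid_csv(round(vals, 12)), chemical)
}

# independent scalar transcription of the five-variable dose formula
dose_formula_oracle <- function(C, IR, class, EF, ED, AT, BW) {
  if (class == "mass_per_day") {
    C * (IR * 1e-3) * EF * ED / (AT * BW)
  } else {
    C * IR * EF * ED / AT
  }
}

# brute-force regrouping oracle: replicate each age group's ADD by its
# length in months, then take plain means within each lifestage
month_expansion_oracle <- function(add_tbl) {
  months <- c(1, 2, 3, 6, 12, 12, 36, 60, 60, 60, 588)
  names(months) <- age_group_roster()$age_group
  map <- lifestage_map()
  out <- list()
  for (m in unique(as.character(add_tbl$medium))) {
    rows <- add_tbl[add_tbl$medium == m, ]
    expanded <- rep(rows$add, times = months[as.character(rows$age_group)])
    stage_of <- rep(
      map$lifestage[match(as.character(rows$age_group), map$age_group)],
      times = months[as.character(rows$age_group)]
    )
    out[[m]] <- tapply(expanded, stage_of, mean)
  }
  out
}

chronic_factors_one_medium <- function(medium, intake_rate, body_weight = 15) {
  ages <- age_group_roster()
  roster <- media_roster()
  units <- c(
    mass_per_day = "mg/day", volume_per_kg_day = "mL/kg-day",
    mass_per_kg_day = "g/kg-day"
  )
  unit <- units[[roster$intake_unit_class[roster$medium == medium]]]
  tibble::tibble(
    medium = medium,
    age_group = ages$age_group,
    intake_rate = intake_rate,
    intake_unit = unit,
    exposure_frequency = 365,
    exposure_duration = ages$span_years,
    averaging_time = ages$span_years * 365,
    body_weight = body_weight
  )
}
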