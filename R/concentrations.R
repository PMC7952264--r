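#' Summarise concentration samples under a non-detect policy
#'
#' Computes the arithmetic mean concentration for one medium from raw
#' samples, substituting censored (below limit-of-detection) observations
#' according to a policy:
#' \describe{
#'   \item{`exclude`}{drop censored samples; the mean is over detects only.
#'     If every sample is censored the mean is returned as `NA` with
#'     `mean_defined = FALSE`, never silently 0.}
#'   \item{`lod_over_sqrt2`}{substitute \eqn{LOD/\sqrt{2}} for each
#'     censored sample.}
#'   \item{`half_lod_split`}{substitute the full LOD for the first half of
#'     the censored samples (in input order; an odd count gives the extra
#'     sample the full LOD) and LOD/2 for the rest.}
#'   \item{`zero`}{substitute 0.}
#' }
#' A censored sample's LOD is the midpoint of `(lod_low, lod_high)`; give
#' both the same value for a point detection limit.
#'
#' @param samples tibble with columns `medium`, `value` (NA when censored),
#'   `lod_low`, `lod_high`, `detected` (logical). One medium per call.
#' @param policy one of `"exclude"` (default), `"lod_over_sqrt2"`,
#'   `"half_lod_split"`, `"zero"`.
#' @return A one-row tibble: `medium`, `mean`, `n`, `n_detected`,
#'   `pct_above_lod`, `median`, `sd`, `policy`, `mean_defined`.
#' @examples
#' s <- tibble::tibble(
#'   medium = "water", value = c(1, 2, 3, NA), detected = c(TRUE, TRUE, TRUE, FALSE),
#'   lod_low = 0.5, lod_high = 0.5
#' )
#' summarize_concentrations(s, "lod_over_sqrt2")
#' @export
summarize_concentrations <- function(samples,
                                     policy = c(
                                       "exclude", "lod_over_sqrt2",
                                       "half_lod_split", "zero"
                                     )) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(samples), nrow(samples) > 0)
  req <- c("medium", "value", "detected")
  miss <- setdiff(req, names(samples))
  if (length(miss) > 0) {
    stop("samples table lacks column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (dplyr::n_distinct(samples$medium) != 1) {
    stop("summarize_concentrations expects samples from a single medium",
      call. = FALSE
    )
  }
  if (!"lod_low" %in% names(samples)) samples$lod_low <- NA_real_
  if (!"lod_high" %in% names(samples)) samples$lod_high <- samples$lod_low
  if (any(samples$detected & (is.na(samples$value) | samples$value < 0))) {
    stop("detected samples must carry a value >= 0", call. = FALSE)
  }
  cens <- !samples$detected
  lod <- (samples$lod_low + samples$lod_high) / 2
  if (policy != "exclude" && any(cens & is.na(lod))) {
    stop("censored samples need a usable LOD for policy '", policy, "'",
      call. = FALSE
    )
  }
  vals <- samples$value
  if (policy == "lod_over_sqrt2") {
    vals[cens] <- lod[cens] / sqrt(2)
  } else if (policy == "zero") {
    vals[cens] <- 0
  } else if (policy == "half_lod_split") {
    idx <- which(cens) # input order; first ceil(k/2) get the full LOD
    k <- length(idx)
    if (k > 0) {
      hi <- idx[seq_len(ceiling(k / 2))]
      lo <- setdiff(idx, hi)
      vals[hi] <- lod[hi]
      vals[lo] <- lod[lo] / 2
    }
  } else { # exclude
    vals <- vals[!cens]
  }
  defined <- length(vals) > 0
  tibble::tibble(
    medium = samples$medium[1],
    mean = if (defined) mean(vals) else NA_real_,
    n = nrow(samples),
    n_detected = sum(samples$detected),
    pct_above_lod = 100 * sum(samples$detected) / nrow(samples),
    median = if (defined) stats::median(vals) else NA_real_,
    sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
    policy = policy,
    mean_defined = defined
  )
}

#' Sum component means as a proxy concentration
#'
#' Estimates a parent chemical's concentration in a medium by summing the
#' mean concentrations of measured components (e.g. metabolites measured in
#' breastmilk as a proxy for the parent compound). Component provenance is
#' retained in the `source` column.
#'
#' @param components tibble with columns `name` and `mean` (shared units).
#' @param medium the medium the proxy applies to.
#' @return A one-row tibble: `medium`, `mean`, `n_components`, `source`.
#' @examples
#' metabolite_sum_proxy(
#'   tibble::tibble(name = c("m1", "m2"), mean = c(2e-4, 5e-4)), "breastmilk"
#' )
#' @export
metabolite_sum_proxy <- function(components, medium) {
  stopifnot(is.data.frame(components))
  if (nrow(components) == 0) {
    stop("metabolite_sum_proxy needs at least one component", call. = FALSE)
  }
  if (!all(c("name", "mean") %in% names(components))) {
    stop("components need 'name' and 'mean' columns", call. = FALSE)
  }
  if (any(components$mean < 0)) stop("component means must be >= 0", call. = FALSE)
  tibble::tibble(
    medium = medium,
    mean = sum(components$mean),
    n_components = nrow(components),
    source = paste0("sum of components: ", paste(components$name, collapse = " + "))
  )
}

#' Packaged case-example concentration tables
#'
#' Mean media concentrations for three worked case examples, transcribed
#' from published summary tables: the plasticiser DEHP
#' (di[2-ethylhexyl] phthalate), the essential nutrient manganese, and the
#' insecticide degradate endosulfan sulfate before (1994--2010) and after
#' (2011--2016) the US phase-out. Values are study-level summary statistics
#' (mean, median, SD, sample counts, detection frequency, LOD range), not
#' raw samples. The endosulfan fixtures carry only the food media the
#' source monitoring program reported (six pre, two post phase-out); other
#' media are treated as absent downstream and yield explicit zero dose
#' columns.
#'
#' @param chemical one of `"dehp"`, `"manganese"`, `"endosulfan_pre"`,
#'   `"endosulfan_post"`.
#' @return A tibble with columns `medium`, `unit`, `n`, `pct_above_lod`,
#'   `lod_low`, `lod_high`, `mean`, `median`, `sd`, `source`; one row per
#'   medium present in the source table. Concentrations in mg/g (solids,
#'   foods) or mg/mL (liquids).
#' @examples
#' load_fixture("dehp")
#' @export
load_fixture <- function(chemical = c(
                           "dehp", "manganese",
                           "endosulfan_pre", "endosulfan_post"
                         )) {
  chemical <- match.arg(chemical)
  path <- system.file("extdata", paste0("fixture_", chemical, ".csv"),
    package = "aggexpo", mustWork = TRUE
  )
  readr::read_csv(path,
    col_types = readr::cols(
      medium = "c", unit = "c", n = "i", pct_above_lod = "d",
      lod_low = "d", lod_high = "d", mean = "d", median = "d",
      sd = "d", source = "c"
    )
  )
}

#' @rdname load_fixture
#' @return `fixture_names()`: the available fixture identifiers.
#' @export
fixture_names <- function() {
  c("dehp", "manganese", "endosulfan_pre", "endosulfan_post")
}

#' Simulate censored concentration samples
#'
#' Draws lognormal concentration samples for one or more media and censors
#' a fixed fraction at a generated detection limit: the lowest
#' `round(censoring_fraction * n)` samples of each medium are marked
#' non-detected, with the LOD set at the censoring threshold. The
#' generating distribution's closed-form mean,
#' \eqn{\exp(\mu + \sigma^2/2)}, is attached as attribute `true_mean` so
#' recovery by [summarize_concentrations()] can be validated.
#'
#' @param n samples per medium.
#' @param n_media how many canonical media to simulate (in roster order).
#' @param censoring_fraction proportion of samples censored, in \[0, 1\].
#' @param meanlog,sdlog lognormal parameters on the log scale.
#' @param seed integer seed; the same seed reproduces the same table.
#' @return A tibble of samples (`medium`, `value`, `lod_low`, `lod_high`,
#'   `detected`) with attribute `true_mean`.
#' @examples
#' s <- simulate_concentration_samples(50, censoring_fraction = 0.2, seed = 1)
#' summarize_concentrations(s, "exclude")
#' @export
simulate_concentration_samples <- function(n = 100, n_media = 1,
                                           censoring_fraction = 0,
                                           meanlog = log(1e-3), sdlog = 1,
                                           seed = NULL) {
  if (censoring_fraction < 0 || censoring_fraction > 1) {
    stop("censoring_fraction must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n >= 1, n_media >= 1, n_media <= nrow(media_roster()), sdlog >= 0)
  draw <- function() {
    media <- media_roster()$medium[seq_len(n_media)]
    purrr::map_dfr(media, function(m) {
      v <- stats::rlnorm(n, meanlog, sdlog)
      k <- round(censoring_fraction * n)
      ord <- order(v)
      cens <- seq_along(v) %in% ord[seq_len(k)]
      lod <- if (k > 0) max(v[cens]) else NA_real_
      tibble::tibble(
        medium = m,
        value = ifelse(cens, NA_real_, v),
        lod_low = ifelse(cens, lod, NA_real_),
        lod_high = ifelse(cens, lod, NA_real_),
        detected = !cens
      )
    })
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  attr(out, "true_mean") <- exp(meanlog + sdlog^2 / 2)
  out
}

#' Bundled representative exposure factors
#'
#' A complete chronic-scenario exposure-factor table for the eleven
#' canonical age groups and ten media: per-capita central-tendency intake
#' rates and mean body weights of representative magnitude for a US
#' general population (documented placeholders -- they are of
#' Exposure Factors Handbook style and scale but are not a transcription
#' of any handbook edition), with exposure frequency 365 days/year,
#' exposure duration equal to the age-group span and averaging time equal
#' to the duration in days, so each dose reduces to its concentration times
#' intake rate. Soil and dust intake rates are zero for the birth--<1 month
#' group, where hand-to-mouth soil/dust ingestion data are unavailable;
#' breastmilk intake is zero after the first year and water intake is small
#' before it (exclusively breastfed scenario).
#'
#' @return A tibble with columns `medium`, `age_group`, `intake_rate`,
#'   `intake_unit`, `exposure_frequency`, `exposure_duration`,
#'   `averaging_time`, `body_weight` (110 rows).
#' @examples
#' default_exposure_factors()
#' @export
default_exposure_factors <- function() {
  ages <- age_group_roster()
  bw <- c(4.8, 5.6, 7.4, 9.2, 11.4, 13.8, 18.6, 31.8, 56.8, 71.6, 80.0)
  ir <- list(
    soil       = c(0, 10, 20, 30, 50, 50, 50, 50, 50, 50, 20),
    dust       = c(0, 20, 30, 40, 60, 60, 60, 60, 60, 60, 30),
    water      = c(5, 10, 15, 20, 27, 23, 16, 10, 7, 8, 13),
    breastmilk = c(150, 140, 110, 83, 0, 0, 0, 0, 0, 0, 0),
    dairy      = c(1, 2, 5, 10, 43, 34, 27, 17, 9, 7, 6),
    meat       = c(0, 0.1, 0.5, 2, 4, 3.6, 3.2, 2.3, 1.5, 1.3, 2.5),
    fish       = c(0, 0, 0.1, 0.2, 0.3, 0.4, 0.4, 0.3, 0.2, 0.2, 0.5),
    vegetables = c(0.5, 1, 2, 4, 6.9, 6.7, 5.8, 4.2, 2.9, 2.5, 3.0),
    fruit      = c(0.5, 1, 3, 6, 9.4, 8.5, 6.8, 3.7, 2.0, 1.6, 2.2),
    grains     = c(0.5, 1, 2, 4, 6.4, 6.2, 5.6, 4.2, 2.7, 2.3, 2.0)
  )
  units <- c(
    mass_per_day = "mg/day", volume_per_kg_day = "mL/kg-day",
    mass_per_kg_day = "g/kg-day"
  )
  roster <- media_roster()
  purrr::map_dfr(roster$medium, function(m) {
    tibble::tibble(
      medium = m,
      age_group = ages$age_group,
      intake_rate = ir[[m]],
      intake_unit = units[[roster$intake_unit_class[roster$medium == m]]],
      exposure_frequency = 365,
      exposure_duration = ages$span_years,
      averaging_time = ages$span_years * 365,
      body_weight = bw
    )
  })
}

#' Simulate an exposure-factor table
#'
#' Perturbs the bundled representative factor table with lognormal
#' multiplicative noise on intake rates and body weights (coefficient of
#' variation `cv`), keeping the chronic-scenario time terms and structural
#' zeros (soil/dust for newborns, breastmilk after infancy) intact.
#'
#' @param seed integer seed for reproducibility.
#' @param cv coefficient of variation of the multiplicative noise.
#' @return An exposure-factor tibble in the layout of
#'   [default_exposure_factors()].
#' @export
simulate_exposure_factors <- function(seed = NULL, cv = 0.2) {
  stopifnot(cv >= 0)
  base <- default_exposure_factors()
  sdl <- sqrt(log(1 + cv^2))
  draw <- function() {
    noise_ir <- stats::rlnorm(nrow(base), -sdl^2 / 2, sdl)
    noise_bw <- stats::rlnorm(nrow(base), -sdl^2 / 2, sdl)
    dplyr::mutate(base,
      intake_rate = .data$intake_rate * noise_ir,
      body_weight = .data$body_weight * noise_bw
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Read and write exposure-factor and concentration CSV files
#'
#' `read_exposure_factors()` reads a CSV with columns `medium`,
#' `age_group`, `intake_rate`, `intake_unit`, `exposure_frequency`,
#' `exposure_duration`, `averaging_time`, `body_weight`;
#' `read_concentration_samples()` reads raw samples (`medium`, `value`,
#' `lod_low`, `lod_high`, `detected`).
#'
#' @param path CSV file path.
#' @return A tibble in the corresponding layout.
#' @export
read_exposure_factors <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    medium = "c", age_group = "c", intake_rate = "d", intake_unit = "c",
    exposure_frequency = "d", exposure_duration = "d",
    averaging_time = "d", body_weight = "d"
  ))
  bad <- setdiff(x$medium, media_roster()$medium)
  if (length(bad) > 0) stop("unknown medium: ", paste(bad, collapse = ", "), call. = FALSE)
  bad_age <- setdiff(x$age_group, age_group_roster()$age_group)
  if (length(bad_age) > 0) {
    stop("unknown age group: ", paste(bad_age, collapse = ", "), call. = FALSE)
  }
  x
}

#' @rdname read_exposure_factors
#' @export
read_concentration_samples <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    medium = "c", value = "d", lod_low = "d", lod_high = "d",
    detected = "l"
  ))
}
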