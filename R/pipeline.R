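#' Build and validate a run configuration
#'
#' A run configuration describes one deterministic end-to-end analysis:
#' where the concentrations come from (a packaged fixture, a raw
#' concentration-sample CSV summarised under a non-detect policy, or an
#' already-computed ADD grid), which exposure factors to use (bundled
#' defaults, a CSV, or a seeded synthetic table), the lifespan, and the
#' graph options. Exactly one input mode must be set.
#'
#' @param chemical chemical name used in filenames and titles.
#' @param input_mode one of `"fixture"`, `"concentration_file"`,
#'   `"add_table_file"`.
#' @param fixture fixture name (see [fixture_names()]) for fixture mode.
#' @param concentration_file raw-sample CSV for concentration mode.
#' @param add_table_file ADD-grid CSV for add-table mode.
#' @param nondetect_policy policy for [summarize_concentrations()].
#' @param factor_source `"bundled_default"`, `"file"`, or `"synthetic"`.
#' @param factor_file factor CSV when `factor_source = "file"`.
#' @param seed integer seed for synthetic factors.
#' @param lifespan_years lifespan for LADD weighting.
#' @param out_dir output directory (created by [run_pipeline()]).
#' @param pathway,aggregate_add,format graph-suite options (see
#'   [render_suite()] and [render_add_graphs()]).
#' @param reference_lines optional tibble (`label`, `value`).
#' @param log_level `"info"`, `"warn"` or `"quiet"`.
#' @return A validated config list of class `aggexpo_config`.
#' @export
run_config <- function(chemical = "chemical",
                       input_mode = c("fixture", "concentration_file", "add_table_file"),
                       fixture = NULL, concentration_file = NULL,
                       add_table_file = NULL,
                       nondetect_policy = "exclude",
                       factor_source = c("bundled_default", "file", "synthetic"),
                       factor_file = NULL, seed = 1L,
                       lifespan_years = 70, out_dir = "aggexpo_run",
                       pathway = FALSE, aggregate_add = FALSE,
                       format = "png", reference_lines = NULL,
                       log_level = c("info", "warn", "quiet")) {
  input_mode <- match.arg(input_mode)
  factor_source <- match.arg(factor_source)
  log_level <- match.arg(log_level)
  given <- c(
    fixture = !is.null(fixture),
    concentration_file = !is.null(concentration_file),
    add_table_file = !is.null(add_table_file)
  )
  if (sum(given) > 1) {
    stop("config must set exactly one input source, got: ",
      paste(names(given)[given], collapse = ", "),
      call. = FALSE
    )
  }
  need <- switch(input_mode,
    fixture = fixture, concentration_file = concentration_file,
    add_table_file = add_table_file
  )
  if (is.null(need)) {
    stop("input_mode '", input_mode, "' needs a matching input (",
      input_mode, " = ...)",
      call. = FALSE
    )
  }
  if (input_mode == "fixture" && !fixture %in% fixture_names()) {
    stop("unknown fixture: ", fixture, call. = FALSE)
  }
  if (factor_source == "file" && is.null(factor_file)) {
    stop("factor_source 'file' needs factor_file", call. = FALSE)
  }
  stopifnot(lifespan_years > 0)
  structure(
    list(
      chemical = chemical, input_mode = input_mode, fixture = fixture,
      concentration_file = concentration_file,
      add_table_file = add_table_file,
      nondetect_policy = nondetect_policy,
      factor_source = factor_source, factor_file = factor_file,
      seed = as.integer(seed), lifespan_years = lifespan_years,
      out_dir = out_dir, pathway = isTRUE(pathway),
      aggregate_add = isTRUE(aggregate_add), format = format,
      reference_lines = reference_lines, log_level = log_level
    ),
    class = "aggexpo_config"
  )
}

#' @rdname run_config
#' @param path YAML config file; keys mirror the `run_config()` arguments.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$reference_lines)) {
    raw$reference_lines <- dplyr::bind_rows(raw$reference_lines)
  }
  do.call(run_config, raw)
}

#' Run the full exposure pipeline
#'
#' Executes the staged analysis described by a config: resolve
#' concentrations (fixture / summarised samples) or import an ADD grid,
#' assemble the age-group dose table, regroup into lifestages with LADD
#' and percent contributions, write all tables and figures (with sidecar
#' CSVs), and write a JSON manifest recording the config, a config hash,
#' every file produced, the stages run and any warnings. Runs are
#' deterministic: the same config and seed reproduce byte-identical
#' tables and sidecars.
#'
#' @param config an `aggexpo_config` from [run_config()] or
#'   [read_run_config()].
#' @return The manifest, invisibly (a list; also written to
#'   `out_dir/manifest.json`).
#' @examples
#' \donttest{
#' cfg <- run_config("DEHP",
#'   input_mode = "fixture", fixture = "dehp",
#'   out_dir = file.path(tempdir(), "dehp_run")
#' )
#' m <- run_pipeline(cfg)
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "aggexpo_config"))
  t0 <- Sys.time()
  warnings_seen <- character()
  note <- function(...) {
    if (config$log_level == "info") message("[aggexpo] ", ...)
  }
  stages <- character()
  files <- character()
  run_stage <- function(name, expr) {
    stages <<- c(stages, name)
    note("stage: ", name)
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(config$out_dir)) {
    stop("cannot create output directory: ", config$out_dir, call. = FALSE)
  }
  add_path <- file.path(config$out_dir, "add_table.csv")

  if (config$input_mode == "add_table_file") {
    add_tbl <- run_stage(
      "import_add_table",
      import_add_table(config$add_table_file, config$chemical)
    )
  } else {
    conc <- if (config$input_mode == "fixture") {
      run_stage("load_fixture", load_fixture(config$fixture))
    } else {
      run_stage("summarize_concentrations", {
        samples <- read_concentration_samples(config$concentration_file)
        purrr::map_dfr(
          split(samples, samples$medium),
          summarize_concentrations,
          policy = config$nondetect_policy
        )
      })
    }
    factors <- run_stage("exposure_factors", switch(config$factor_source,
      bundled_default = default_exposure_factors(),
      file = read_exposure_factors(config$factor_file),
      synthetic = simulate_exposure_factors(seed = config$seed)
    ))
    add_tbl <- run_stage(
      "build_add_table",
      build_add_table(conc, factors, config$chemical)
    )
  }
  run_stage("export_add_table", export_add_table(add_tbl, add_path))
  files <- c(files, add_path)

  doses <- run_stage(
    "regroup_lifestages",
    regroup_lifestages(add_tbl, lifespan_years = config$lifespan_years)
  )
  absent <- unique(as.character(add_tbl$medium[add_tbl$provenance == "absent"]))
  if (length(absent) > 0) {
    warnings_seen <- c(warnings_seen, paste0(
      "build: media absent from input, zero-filled: ",
      paste(absent, collapse = ", ")
    ))
  }
  tabs <- run_stage(
    "write_lifestage_tables",
    write_lifestage_tables(doses, config$out_dir)
  )
  files <- c(files, tabs)

  figs <- run_stage("render_suite", render_suite(
    doses, config$out_dir,
    pathway = config$pathway, format = config$format,
    reference_lines = config$reference_lines
  ))
  files <- c(files, figs$file, figs$sidecar)
  if (config$aggregate_add) {
    figs2 <- run_stage("render_add_graphs", render_add_graphs(
      doses, config$out_dir,
      format = config$format,
      reference_lines = config$reference_lines
    ))
    files <- c(files, figs2$file, figs2$sidecar)
  }

  pct <- percent_contributions(doses)
  empty_rows <- unique(as.character(pct$lifestage[pct$empty]))
  if (length(empty_rows) > 0) {
    warnings_seen <- c(warnings_seen, paste0(
      "percent: zero-total rows flagged empty: ",
      paste(empty_rows, collapse = ", ")
    ))
  }
  cfg_plain <- unclass(config)
  cfg_plain$reference_lines <- if (is.null(config$reference_lines)) {
    NULL
  } else {
    as.data.frame(config$reference_lines)
  }
  manifest <- list(
    tool = "aggexpo",
    version = as.character(utils::packageVersion("aggexpo")),
    chemical = config$chemical,
    config = cfg_plain,
    # hash the analysis-relevant fields only, not where results are written
    config_hash = digest::digest(
      cfg_plain[setdiff(names(cfg_plain), c("out_dir", "log_level"))],
      algo = "sha256"
    ),
    lifestages = lifestage_levels(),
    stages = stages,
    files = basename(files),
    out_dir = normalizePath(config$out_dir),
    warnings = warnings_seen,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(
    manifest[setdiff(names(manifest), "elapsed_s")],
    manifest_path,
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null"
  )
  manifest$files <- c(manifest$files, "manifest.json")
  if (config$log_level != "quiet" && length(warnings_seen) > 0) {
    for (w in warnings_seen) message("[aggexpo] warning: ", w)
  }
  invisible(manifest)
}

#' Write lifestage dose tables as CSV grids
#'
#' Writes three CSVs in the media-by-lifestage grid layout (lifestage
#' columns `young_infant` ... `adult`, then `childhood`, `adult_agg`,
#' `lifetime`): `lifestage_add.csv`, `lifestage_ladd.csv`,
#' `lifestage_percent.csv`, plus a long-format `lifestage_doses.csv`
#' (the [tidy()] output) for machine consumption.
#'
#' @param x a `lifestage_dose` object.
#' @param out_dir output directory.
#' @return Paths of the files written.
#' @export
write_lifestage_tables <- function(x, out_dir) {
  td <- tidy(x)
  wide <- function(col) {
    w <- tidyr::pivot_wider(
      td[, c("medium", "lifestage", col)],
      names_from = "lifestage", values_from = dplyr::all_of(col)
    )
    w[match(media_roster()$medium, w$medium), ]
  }
  paths <- file.path(out_dir, c(
    "lifestage_add.csv", "lifestage_ladd.csv",
    "lifestage_percent.csv", "lifestage_doses.csv"
  ))
  write_csv_full(wide("add"), paths[1])
  write_csv_full(wide("ladd"), paths[2])
  write_csv_full(wide("percent"), paths[3])
  write_csv_full(td, paths[4])
  paths
}

#' Compare two pipeline runs
#'
#' Computes per (lifestage, medium) ADD and LADD differences and ratios
#' between two completed runs (e.g. before and after a regulatory
#' phase-out). Ratios with a zero baseline are returned `NA` and flagged
#' rather than infinite.
#'
#' @param manifest_a,manifest_b manifests returned by [run_pipeline()], or
#'   paths to run directories / `manifest.json` files. Run A is the
#'   baseline.
#' @return A tibble with columns `row_type`, `lifestage`, `medium`,
#'   `add_a`, `add_b`, `add_delta`, `add_ratio`, `ladd_a`, `ladd_b`,
#'   `ladd_delta`, `ladd_ratio`, `ratio_defined`.
#' @export
compare_runs <- function(manifest_a, manifest_b) {
  a <- load_run_doses(manifest_a)
  b <- load_run_doses(manifest_b)
  key <- c("row_type", "lifestage", "medium")
  if (!identical(
    a[order(a$lifestage, a$medium), key],
    b[order(b$lifestage, b$medium), key]
  )) {
    stop("runs use different lifestage mappings or media; cannot compare",
      call. = FALSE
    )
  }
  x <- dplyr::inner_join(a, b, by = key, suffix = c("_a", "_b"))
  dplyr::transmute(x,
    row_type = .data$row_type, lifestage = .data$lifestage,
    medium = .data$medium,
    add_a = .data$add_a, add_b = .data$add_b,
    add_delta = .data$add_b - .data$add_a,
    add_ratio = ifelse(.data$add_a == 0, NA_real_, .data$add_b / .data$add_a),
    ladd_a = .data$ladd_a, ladd_b = .data$ladd_b,
    ladd_delta = .data$ladd_b - .data$ladd_a,
    ladd_ratio = ifelse(.data$ladd_a == 0, NA_real_, .data$ladd_b / .data$ladd_a),
    ratio_defined = .data$add_a != 0
  )
}

load_run_doses <- function(m) {
  dir <- if (is.list(m)) {
    m$out_dir
  } else if (dir.exists(m)) {
    m
  } else {
    dirname(m)
  }
  path <- file.path(dir, "lifestage_doses.csv")
  if (!file.exists(path)) {
    stop("no lifestage_doses.csv found under ", dir, call. = FALSE)
  }
  readr::read_csv(path, col_types = readr::cols(
    row_type = "c", lifestage = "c", medium = "c", years = "d",
    add = "d", ladd = "d", percent = "d", empty = "l"
  ))
}
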