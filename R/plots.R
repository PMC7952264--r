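#' Graph families for lifestage dose tables
#'
#' Five stacked-bar graph families summarise a lifestage dose table:
#' \describe{
#'   \item{`add_by_lifestage`}{aggregate ADD per lifestage, media stacked;
#'     childhood/adult/lifetime aggregate bars appended (visually
#'     separated) by default.}
#'   \item{`ladd_by_lifestage`}{aggregate LADD per lifestage (time-scaled
#'     ADD); aggregates excluded by default.}
#'   \item{`percent_add_by_lifestage`}{percent media contribution within
#'     each lifestage; every bar totals 100 unless the lifestage has zero
#'     total dose (flagged-empty bars stay at zero); aggregates included
#'     by default.}
#'   \item{`add_single_medium` / `ladd_single_medium`}{one medium's ADD or
#'     LADD across lifestages.}
#' }
#' Bars run chronologically (young infant to adult); media stack in the
#' fixed canonical order with a fixed colour map, identical across all
#' figures of a run. Optional horizontal reference lines (e.g. a reference
#' dose, adequate intake or tolerable upper intake level) can be drawn on
#' dose-scale graphs.
#'
#' @param x a `lifestage_dose` object.
#' @param graph_type one of the five family names above.
#' @param medium required for the single-medium families; one of the ten
#'   canonical media.
#' @param include_aggregates override the per-family default described
#'   above.
#' @param reference_lines optional tibble with columns `label` and `value`
#'   (mg/kg-day).
#' @return `plot_doses()`: a ggplot object. `graph_data()`: the tibble of
#'   exactly the values plotted (`lifestage`, `medium`, `value`, `unit`).
#' @examples
#' add <- build_add_table(load_fixture("manganese"), default_exposure_factors(), "Mn")
#' ls <- regroup_lifestages(add)
#' plot_doses(ls, "add_by_lifestage",
#'   reference_lines = tibble::tibble(label = "RfD", value = 0.14)
#' )
#' @export
plot_doses <- function(x, graph_type = graph_types(), medium = NULL,
                       include_aggregates = NULL, reference_lines = NULL) {
  graph_type <- match.arg(graph_type)
  dat <- graph_data(x, graph_type, medium, include_aggregates)
  percent <- graph_type == "percent_add_by_lifestage"
  ylab <- if (percent) {
    "Contribution to lifestage ADD (%)"
  } else if (grepl("^ladd", graph_type)) {
    "LADD (mg/kg-day)"
  } else {
    "ADD (mg/kg-day)"
  }
  dat$section <- factor(
    ifelse(as.character(dat$lifestage) %in% aggregate_levels(),
      "aggregates", "lifestages"
    ),
    levels = c("lifestages", "aggregates")
  )
  p <- ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$lifestage, y = .data$value, fill = .data$medium
  )) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::scale_fill_manual(values = media_colors(), drop = FALSE) +
    ggplot2::labs(
      title = paste0(x$chemical, ": ", gsub("_", " ", graph_type),
        if (!is.null(medium)) paste0(" (", medium, ")") else ""
      ),
      x = "Lifestage", y = ylab, fill = "Medium"
    ) +
    ggplot2::theme_minimal(base_size = 11) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (dplyr::n_distinct(dat$section) > 1) {
    p <- p + ggplot2::facet_grid(
      cols = ggplot2::vars(.data$section),
      scales = "free_x", space = "free_x"
    )
  }
  if (!is.null(reference_lines) && !percent && nrow(reference_lines) > 0) {
    p <- p +
      ggplot2::geom_hline(
        data = reference_lines,
        ggplot2::aes(yintercept = .data$value),
        linetype = "dashed", colour = "grey30"
      ) +
      ggplot2::annotate("text",
        x = Inf, y = reference_lines$value,
        label = reference_lines$label, hjust = 1.05, vjust = -0.4, size = 3
      )
  }
  p
}

#' @rdname plot_doses
#' @export
graph_types <- function() {
  c(
    "add_by_lifestage", "ladd_by_lifestage", "percent_add_by_lifestage",
    "add_single_medium", "ladd_single_medium"
  )
}

#' @rdname plot_doses
#' @export
graph_data <- function(x, graph_type = graph_types(), medium = NULL,
                       include_aggregates = NULL) {
  stopifnot(inherits(x, "lifestage_dose"))
  graph_type <- match.arg(graph_type)
  single <- graph_type %in% c("add_single_medium", "ladd_single_medium")
  if (single) {
    if (is.null(medium) || !medium %in% media_roster()$medium) {
      stop("single-medium graphs need a canonical medium, got: ",
        if (is.null(medium)) "NULL" else medium,
        call. = FALSE
      )
    }
  }
  if (is.null(include_aggregates)) {
    # ADD and percent graphs carry aggregate bars; LADD and pathway graphs do not
    include_aggregates <- graph_type %in% c(
      "add_by_lifestage", "percent_add_by_lifestage"
    )
  }
  dat <- switch(graph_type,
    add_by_lifestage = ,
    add_single_medium = dplyr::transmute(x$doses,
      row_type = .data$row_type, lifestage = .data$lifestage,
      medium = .data$medium, value = .data$add, unit = "mg/kg-day"
    ),
    ladd_by_lifestage = ,
    ladd_single_medium = dplyr::transmute(x$doses,
      row_type = .data$row_type, lifestage = .data$lifestage,
      medium = .data$medium, value = .data$ladd, unit = "mg/kg-day"
    ),
    percent_add_by_lifestage = dplyr::transmute(percent_contributions(x),
      row_type = .data$row_type, lifestage = .data$lifestage,
      medium = .data$medium, value = .data$percent, unit = "percent"
    )
  )
  if (!include_aggregates) dat <- dat[dat$row_type == "lifestage", ]
  if (single) dat <- dat[as.character(dat$medium) == medium, ]
  tibble::as_tibble(dat[, c("lifestage", "medium", "value", "unit")])
}

#' Fixed colour map for the ten canonical media
#'
#' @return Named character vector of hex colours in canonical stacking
#'   order; identical across every figure of a run.
#' @export
media_colors <- function() {
  stats::setNames(
    c(
      "#8c510a", "#bf812d", "#35978f", "#c51b7d", "#fde0ef",
      "#d73027", "#4575b4", "#1a9850", "#fdae61", "#f6e8c3"
    ),
    media_roster()$medium
  )
}

#' Render one graph to file with a plotted-data sidecar
#'
#' Writes the figure and, alongside it, a machine-readable sidecar CSV
#' (`<figure>.data.csv`, columns `lifestage`, `medium`, `value`, `unit`)
#' containing exactly the plotted values. All testing of figures is done
#' against sidecars, never pixels.
#'
#' @inheritParams plot_doses
#' @param path output file; the extension selects the device (`png`,
#'   `pdf`, or `svg` where cairo is available).
#' @param width,height figure size in inches.
#' @return Invisibly, a tibble with columns `file` and `sidecar`.
#' @export
render_graph <- function(x, graph_type, path, medium = NULL,
                         include_aggregates = NULL, reference_lines = NULL,
                         width = 7, height = 4.5) {
  fmt <- tolower(tools::file_ext(path))
  if (!fmt %in% c("png", "pdf", "svg")) {
    stop("unsupported figure format: '", fmt, "' (use png, pdf or svg)",
      call. = FALSE
    )
  }
  if (fmt == "svg" && !capabilities("cairo")) {
    stop("svg output needs cairo support in this R build; use png or pdf",
      call. = FALSE
    )
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("output directory does not exist: ", dir, call. = FALSE)
  }
  p <- plot_doses(x, graph_type,
    medium = medium,
    include_aggregates = include_aggregates,
    reference_lines = reference_lines
  )
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 120)
  sidecar <- paste0(path, ".data.csv")
  write_csv_full(
    graph_data(x, graph_type, medium, include_aggregates),
    sidecar
  )
  invisible(tibble::tibble(file = path, sidecar = sidecar))
}

#' Render the standard graph suite for one chemical
#'
#' `render_suite()` emits the five graph families once each (the two
#' single-medium families use the medium with the largest lifetime dose,
#' a deterministic choice); with `pathway = TRUE` it additionally emits
#' ADD and LADD graphs for each of the ten media (20 pathway graphs).
#' `render_add_graphs()` emits the aggregate-ADD set: one all-media ADD
#' graph plus ten medium-specific ADD graphs (11 files). Filenames are
#' deterministic functions of the chemical and graph type.
#'
#' @param x a `lifestage_dose` object.
#' @param out_dir output directory (created if needed).
#' @param pathway also emit the 20 per-medium pathway graphs.
#' @param format `"png"`, `"pdf"` or `"svg"`.
#' @inheritParams plot_doses
#' @return A tibble with columns `graph_type`, `medium`, `file`, `sidecar`.
#' @export
render_suite <- function(x, out_dir, pathway = FALSE, format = "png",
                         reference_lines = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  chem <- slug(x$chemical)
  top <- top_medium(x)
  # the five family exemplars (single-medium ones use the top medium and a
  # medium-free filename), plus, in pathway mode, all 10 media x {ADD, LADD}
  jobs <- tibble::tibble(
    graph_type = graph_types(),
    medium = c(NA, NA, NA, top, top),
    tag_medium = FALSE
  )
  if (pathway) {
    extra <- tidyr::expand_grid(
      graph_type = c("add_single_medium", "ladd_single_medium"),
      medium = media_roster()$medium
    )
    extra$tag_medium <- TRUE
    jobs <- dplyr::bind_rows(jobs, extra)
  }
  out <- purrr::pmap_dfr(jobs, function(graph_type, medium, tag_medium) {
    stem <- if (tag_medium) {
      paste0(chem, "_", graph_type, "_", medium)
    } else {
      paste0(chem, "_", graph_type)
    }
    path <- file.path(out_dir, paste0(stem, ".", format))
    res <- render_graph(x, graph_type, path,
      medium = if (is.na(medium)) NULL else medium,
      reference_lines = reference_lines
    )
    tibble::tibble(
      graph_type = graph_type,
      medium = medium, file = res$file, sidecar = res$sidecar
    )
  })
  out
}

#' @rdname render_suite
#' @export
render_add_graphs <- function(x, out_dir, format = "png",
                              reference_lines = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  chem <- slug(x$chemical)
  jobs <- tibble::tibble(
    graph_type = c("add_by_lifestage", rep("add_single_medium", 10)),
    medium = c(NA, media_roster()$medium)
  )
  purrr::pmap_dfr(jobs, function(graph_type, medium) {
    stem <- if (is.na(medium)) {
      paste0(chem, "_", graph_type)
    } else {
      paste0(chem, "_", graph_type, "_", medium)
    }
    path <- file.path(out_dir, paste0(stem, ".", format))
    res <- render_graph(x, graph_type, path,
      medium = if (is.na(medium)) NULL else medium,
      reference_lines = reference_lines
    )
    tibble::tibble(
      graph_type = graph_type,
      medium = medium, file = res$file, sidecar = res$sidecar
    )
  })
}

#' @method autoplot lifestage_dose
#' @export
autoplot.lifestage_dose <- function(object, graph_type = "add_by_lifestage",
                                    ...) {
  plot_doses(object, graph_type, ...)
}

slug <- function(x) gsub("[^a-z0-9]+", "_", tolower(x))

top_medium <- function(x) {
  lifetime <- x$doses[x$doses$row_type == "aggregate" &
    x$doses$lifestage == "lifetime", ]
  if (all(lifetime$add == 0)) {
    return(media_roster()$medium[1])
  }
  as.character(lifetime$medium[which.max(lifetime$add)])
}
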