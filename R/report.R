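#' Read a suite configuration
#'
#' YAML or JSON file describing which analyses to run. Recognised
#' top-level blocks: `resolution`, `dof`, `color`, `distortion`, plus
#' the globals `min_prominence`, `profile_width`, `output_dir`, `seed`.
#' Each block names its input `image` and the geometric inputs of its
#' engine (profile `line` as `[r0, c0, r1, c1]`, distortion `points`,
#' colour `layout` and `reference`). Geometry is always explicit user
#' data, never inferred from the image, so results stay auditable.
#'
#' @param path Config file path (`.yaml`/`.yml`/`.json`).
#' @return A config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format '.", ext, "'")
  }
  cfg
}

config_line <- function(block, width_px) {
  l <- block$line
  if (is.null(l) || length(l) != 4) {
    stop("config block needs 'line: [r0, c0, r1, c1]'")
  }
  line_segment(c(l[1], l[2]), c(l[3], l[4]), width_px = width_px)
}

config_points <- function(block, base_dir) {
  p <- block$points
  if (is.character(p)) {
    p <- jsonlite::read_json(resolve_path(p, base_dir), simplifyVector = TRUE)
  }
  need <- c("top_left", "top_mid", "top_right",
            "bottom_left", "bottom_mid", "bottom_right")
  if (!all(need %in% names(p))) {
    stop("distortion points must name: ", paste(need, collapse = ", "))
  }
  six_points(p$top_left, p$top_mid, p$top_right,
             p$bottom_left, p$bottom_mid, p$bottom_right)
}

resolve_path <- function(path, base_dir) {
  if (is.null(base_dir) || file.exists(path)) path else file.path(base_dir, path)
}

#' Run the configured analysis suite
#'
#' Executes every configured test independently; an error in one test
#' is captured in its report entry and does not abort the others.
#' Unconfigured tests are reported as `"not_run"`.
#'
#' @param config Config list from [read_config()] (or built in code).
#' @param base_dir Directory against which relative paths in the config
#'   are resolved.
#' @return A `qa_report`: tool version, config echo, per-image md5
#'   checksums, timestamp and one entry per test with `status`
#'   (`"ok"`/`"error"`/`"not_run"`) and the engine result.
#' @export
run_suite <- function(config, base_dir = NULL) {
  prom <- config$min_prominence %||% 5
  width <- config$profile_width %||% 1L
  checksums <- list()
  results <- list()

  run_block <- function(name, fun) {
    block <- config[[name]]
    if (is.null(block)) {
      return(list(status = "not_run", result = NULL))
    }
    tryCatch({
      img_path <- resolve_path(block$image, base_dir)
      image <- read_image(img_path)
      checksums[[block$image]] <<- unname(tools::md5sum(img_path))
      list(status = "ok", result = fun(block, image))
    }, error = function(e) list(status = "error", error = conditionMessage(e)))
  }

  results$resolution <- run_block("resolution", function(block, image) {
    analyze_resolution(image, config_line(block, width),
                       group = block$group,
                       elements = block$elements %||% 1:6,
                       strategy = block$strategy %||% "mean",
                       min_prominence = prom)
  })
  results$dof <- run_block("dof", function(block, image) {
    analyze_dof(image, config_line(block, width),
                lp_per_mm = block$lp_per_mm %||% 5,
                validation_window = block$validation_window %||% 20L,
                min_prominence = prom)
  })
  results$color <- run_block("color", function(block, image) {
    ref <- if (is.character(block$reference)) {
      read_reference_lab(resolve_ref(block$reference, base_dir))
    } else {
      as.data.frame(block$reference)
    }
    lay <- block$layout
    layout <- patch_layout(lay$nrow, lay$ncol, lay$origin, lay$pitch,
                           lay$patch_px,
                           inner_fraction = lay$inner_fraction %||% 0.5)
    analyze_color(image, layout, ref)
  })
  results$distortion <- run_block("distortion", function(block, image) {
    analyze_distortion(image, config_points(block, base_dir),
                       snap = isTRUE(block$snap))
  })

  structure(list(tool = "lapqc",
                 version = as.character(utils::packageVersion("lapqc")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 seed = config$seed %||% NA_integer_,
                 config = config,
                 checksums = checksums,
                 results = results),
            class = "qa_report")
}

resolve_ref <- function(ref, base_dir) {
  if (file.exists(ref)) return(ref)
  cand <- if (!is.null(base_dir)) file.path(base_dir, ref) else ""
  if (file.exists(cand)) cand else ref   # may be a shipped preset name
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a QA report
#'
#' Writes the canonical JSON report, a one-row-per-metric CSV summary,
#' and (when a colour result is present) the reference-vs-measured
#' swatch audit image.
#'
#' @param report A [qa_report][run_suite].
#' @param dir Output directory (created if missing).
#' @param basename File stem for the outputs.
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir, basename = "qa_report") {
  stopifnot(inherits(report, "qa_report"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  json_path <- file.path(dir, paste0(basename, ".json"))
  jsonlite::write_json(report_to_list(report), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  csv_path <- file.path(dir, paste0(basename, ".csv"))
  utils::write.csv(report_summary(report), csv_path, row.names = FALSE)
  paths <- c(json_path, csv_path)

  col <- report$results$color
  if (!is.null(col) && identical(col$status, "ok")) {
    sw_path <- file.path(dir, paste0(basename, "_swatches.png"))
    write_image(swatch_image(col$result), sw_path)
    paths <- c(paths, sw_path)
  }
  invisible(paths)
}

#' Flat metric summary of a report
#'
#' @param report A [qa_report][run_suite].
#' @return Data frame with columns `test`, `metric`, `value`.
#' @export
report_summary <- function(report) {
  rows <- list()
  add <- function(test, metric, value) {
    rows[[length(rows) + 1]] <<- data.frame(test = test, metric = metric,
                                            value = value)
  }
  r <- report$results$resolution
  if (identical(r$status, "ok")) {
    res <- r$result
    if (res$status == "resolved") {
      add("resolution", "limit_group", res$limit$group)
      add("resolution", "limit_element", res$limit$element)
      add("resolution", "limit_lp_mm", res$limit$frequency_lp_mm)
      add("resolution", "limit_um", res$limit_um)
    } else {
      add("resolution", "limit_um", NA_real_)
    }
  }
  d <- report$results$dof
  if (identical(d$status, "ok")) {
    add("dof", "dof_mm", d$result$dof_mm)
    add("dof", "initial_range", d$result$initial_range)
    add("dof", "peaks_before_failure", d$result$peaks_before_failure)
  }
  co <- report$results$color
  if (identical(co$status, "ok")) {
    add("color", "mean_delta_e_ab", co$result$mean_delta_e)
    add("color", "mean_delta_c_ab", co$result$mean_delta_c)
    if (!is.na(co$result$mean_delta_e_wb)) {
      add("color", "mean_delta_e_ab_wb", co$result$mean_delta_e_wb)
      add("color", "mean_delta_c_ab_wb", co$result$mean_delta_c_wb)
    }
  }
  di <- report$results$distortion
  if (identical(di$status, "ok")) {
    add("distortion", "smia_tv_percent", di$result$percent)
    add("distortion", "smia_tv_percent_magnitude", di$result$percent_magnitude)
  }
  if (length(rows) == 0) {
    return(data.frame(test = character(0), metric = character(0),
                      value = numeric(0)))
  }
  do.call(rbind, rows)
}

# Strip classes/closures so the report serializes cleanly to JSON.
report_to_list <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, report_to_list)
    attributes(x) <- list(names = names(x))
    x
  } else if (is.matrix(x)) {
    as.data.frame(x)
  } else {
    x
  }
}

#' Write ground truth as a JSON sidecar
#'
#' @param truth A `lapqc_truth`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "lapqc_truth"))
  jsonlite::write_json(report_to_list(unclass(truth)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null", force = TRUE)
  invisible(path)
}

#' @export
print.qa_report <- function(x, ...) {
  cat("<qa_report>", x$tool, x$version, "at", x$timestamp, "\n")
  for (nm in names(x$results)) {
    cat(sprintf("  %-11s %s\n", nm, x$results[[nm]]$status))
  }
  invisible(x)
}
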