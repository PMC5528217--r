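#' Write an analysis report to CSV or JSON
#'
#' CSV output writes the report's main table (per-fly alpha diversity for a
#' `diversity_report`, the model table for a `qic_table`, the per-fly
#' change table for a `period_comparison`) with confidence intervals as two
#' explicit columns; pair tables go to a `*_pairs.csv` sidecar. JSON output
#' serialises the whole report at full precision, so a round-trip read
#' returns equal values to at least 12 significant digits.
#'
#' @param report A `diversity_report`, `qic_table` or `period_comparison`.
#' @param path Output path; format follows the `.csv`/`.json` extension.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  UseMethod("write_report")
}

report_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("csv", "json")) {
    abort(paste0("unsupported report extension: .", ext))
  }
  ext
}

sidecar <- function(path, tag) {
  sub("\\.csv$", paste0("_", tag, ".csv"), path, ignore.case = TRUE)
}

#' @export
write_report.diversity_report <- function(report, path) {
  if (report_format(path) == "csv") {
    readr::write_csv(report$alpha, path, progress = FALSE)
    if (nrow(report$pairs)) {
      readr::write_csv(report$pairs, sidecar(path, "pairs"), progress = FALSE)
    }
  } else {
    mm <- report$mean_matrix
    jsonlite::write_json(
      list(type = "diversity_report", period = report$period,
           reps = report$reps, seed = report$seed,
           alpha = report$alpha, pairs = report$pairs,
           mean_matrix = cbind(tibble::tibble(plant_id = rownames(mm)),
                               tibble::as_tibble(mm))),
      path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @export
write_report.qic_table <- function(report, path) {
  tab <- tibble::as_tibble(report)
  tab <- tab[order(tab$qic), ]
  if (report_format(path) == "csv") {
    readr::write_csv(tab, path, progress = FALSE)
  } else {
    jsonlite::write_json(
      list(type = "qic_table", period = attr(report, "period"),
           unit = attr(report, "unit"),
           selected = as.character(attr(report, "selected")),
           qic_delta = attr(report, "qic_delta"), models = tab,
           m4_components = attr(report, "m4_components")),
      path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @export
write_report.period_comparison <- function(report, path) {
  if (report_format(path) == "csv") {
    readr::write_csv(report$alpha, path, progress = FALSE)
    if (nrow(report$pairs)) {
      readr::write_csv(report$pairs, sidecar(path, "pairs"), progress = FALSE)
    }
  } else {
    jsonlite::write_json(list(type = "period_comparison",
                              alpha = report$alpha, pairs = report$pairs),
                         path, auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#'
#' @param path JSON report path.
#' @return A list with the report's tables as tibbles; `type` names the
#'   report class it came from.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in intersect(c("alpha", "pairs", "models", "mean_matrix",
                        "m4_components"), names(x))) {
    x[[f]] <- tibble::as_tibble(x[[f]])
  }
  x
}
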