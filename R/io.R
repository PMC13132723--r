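#' Parse day labels that may be given in days or weeks
#'
#' Accepts numbers, `"5"`, `"5d"`, or `"8w"` (weeks are converted at 7 days
#' per week); returns days as numeric.
#'
#' @param x numeric or character vector of day labels.
#' @return Numeric vector of days; `NA` for unparseable entries.
#' @export
parse_days <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  wk <- grepl("^[0-9.]+\\s*w$", x)
  out[wk] <- suppressWarnings(as.numeric(sub("w$", "", sub("\\s", "", x[wk])))) * 7
  dy <- grepl("^[0-9.]+\\s*d$", x)
  out[dy] <- suppressWarnings(as.numeric(sub("d$", "", sub("\\s", "", x[dy]))))
  out
}

density_columns <- c("mouse_id", "group", "day", "region", "cell_type",
                     "density")

#' Read a per-animal density table from a TSV file
#'
#' Expects a tab-separated file with header columns `mouse_id`, `group`
#' (`control`/`treated`), `day` (days, or week labels like `8w`), `region`,
#' `cell_type`, `density` and optionally `unit`. Malformed rows are rejected
#' with their line numbers.
#'
#' @param path file path.
#' @return A validated `DensityTable` data frame (days numeric).
#' @export
read_density_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = TRUE)
  missing_cols <- setdiff(density_columns, names(tab))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"unit" %in% names(tab)) tab$unit <- "cells/mm^2"
  lines <- seq_len(nrow(tab)) + 1L  # header is line 1
  day <- parse_days(tab$day)
  if (anyNA(day)) {
    stop("unparseable day value(s) at line(s): ",
         paste(lines[is.na(day)], collapse = ", "))
  }
  tab$day <- day
  dens <- suppressWarnings(as.numeric(tab$density))
  bad <- is.na(dens) | dens < 0
  if (any(bad)) {
    stop("missing or negative density at line(s): ",
         paste(lines[bad], collapse = ", "))
  }
  tab$density <- dens
  if (!all(tab$group %in% c("control", "treated"))) {
    bad <- !tab$group %in% c("control", "treated")
    stop("group must be 'control' or 'treated'; offending line(s): ",
         paste(lines[bad], collapse = ", "))
  }
  key <- tab[, c("mouse_id", "day", "region", "cell_type")]
  if (anyDuplicated(key)) {
    stop("duplicate (mouse_id, day, region, cell_type) at line(s): ",
         paste(lines[duplicated(key)], collapse = ", "))
  }
  tab[, c(density_columns, "unit")]
}

#' Write a density table as TSV
#'
#' Fixed column order (`mouse_id`, `group`, `day`, `region`, `cell_type`,
#' `density`, `unit`), full numeric precision, no quoting; byte-identical
#' across reruns on identical input.
#'
#' @param table a `DensityTable` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_density_table <- function(table, path) {
  cols <- c(density_columns, if ("unit" %in% names(table)) "unit")
  tab <- table[, cols]
  tab$density <- format(tab$density, digits = 17, trim = TRUE,
                        scientific = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a kinetics report (or any result table) to TSV + JSON
#'
#' Emits `path` as a tab-separated summary table and `<path>.json` as the
#' full structured report at full numeric precision. Reruns on identical
#' input produce identical bytes. An empty report yields a header-only TSV.
#'
#' @param report a `kinetics_report` (see [fit_kinetics_report()]) or a data
#'   frame.
#' @param path output TSV path; the JSON sibling gets `.json` appended.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "kinetics_report")) {
    summary_tab <- report$summary
    full <- unclass(report)
  } else if (is.data.frame(report)) {
    summary_tab <- report
    full <- list(summary = report)
  } else stop("report must be a kinetics_report or a data frame")
  ok <- tryCatch({
    utils::write.table(summary_tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(full, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write report to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path the TSV path passed to [write_report()]; the structured JSON
#'   sibling `<path>.json` is read.
#' @return The report as a list of data frames (class `kinetics_report` when
#'   the components are present).
#' @export
read_report <- function(path) {
  jp <- paste0(path, ".json")
  if (!file.exists(jp)) stop("report JSON not found: ", jp)
  obj <- jsonlite::read_json(jp, simplifyVector = TRUE)
  if (all(c("summary", "tests", "curves") %in% names(obj))) {
    class(obj) <- "kinetics_report"
  }
  obj
}
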