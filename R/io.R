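#' Read an RR tachogram from plain text
#'
#' Reads the simplest interoperable tachogram format: one interval per line,
#' lines starting with `#` ignored. Values are milliseconds by default;
#' `units = "s"` converts seconds to ms on load.
#'
#' @param path Path to a text file with one numeric interval per line.
#' @param units Units of the stored values, `"ms"` (default) or `"s"`.
#' @return An [rr_series()] with beat times accumulated from 0.
#' @export
read_rr_text <- function(path, units = c("ms", "s")) {
  units <- match.arg(units)
  assert_that(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (anyNA(vals)) {
    bad <- idx[which(is.na(vals))[1]]
    stop_hrv(sprintf("cannot parse line %d of %s as a number: '%s'",
                     bad, path, lines[bad]),
             class = "hrv_parse_error")
  }
  assert_that(length(vals) >= 1L, "no intervals found in file")
  if (units == "s") vals <- vals * 1000
  assert_that(all(vals > 0), "non-positive interval in RR file")
  rr_series(vals)
}

#' Write an RR tachogram to plain text
#'
#' One interval (ms) per line, full double precision, so
#' `read_rr_text(write_rr_text(rr, f))` reproduces the intervals exactly.
#'
#' @param rr An [rr_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rr_text <- function(rr, path) {
  validate_rr_series(rr)
  writeLines(formatC(rr$rr, digits = 17, format = "g"), path)
  invisible(path)
}

#' Read an ECG record from CSV
#'
#' Accepts either a single column of voltages (one per line) or a two-column
#' `time,voltage` layout; the layout is auto-detected. For two-column input
#' the time step must agree with `fs` within 1%.
#'
#' @param path Path to the CSV file.
#' @param fs Sampling rate in Hz.
#' @return An [ecg_record()].
#' @export
read_ecg_csv <- function(path, fs) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  assert_that(is_number(fs) && fs > 0, "fs must be a positive number")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  assert_that(length(lines) >= 1L, "empty ECG file")
  # drop a non-numeric header row if present
  first <- strsplit(lines[1], ",")[[1]]
  if (anyNA(suppressWarnings(as.numeric(first)))) lines <- lines[-1]
  assert_that(length(lines) >= 1L, "empty ECG file")
  parts <- strsplit(lines, ",")
  ncols <- length(parts[[1]])
  assert_that(all(lengths(parts) == ncols),
              "inconsistent number of columns in ECG CSV",
              class = "hrv_format_error")
  mat <- suppressWarnings(matrix(as.numeric(unlist(parts)),
                                 ncol = ncols, byrow = TRUE))
  assert_that(!anyNA(mat), "non-numeric value in ECG CSV",
              class = "hrv_parse_error")
  if (ncols == 1L) {
    return(ecg_record(mat[, 1], fs = fs))
  }
  assert_that(ncols == 2L, "ECG CSV must have one or two columns",
              class = "hrv_format_error")
  dt <- diff(mat[, 1])
  assert_that(all(dt > 0), "time column must be strictly increasing",
              class = "hrv_format_error")
  if (abs(median(dt) - 1 / fs) > 0.01 / fs) {
    stop_hrv(sprintf(
      "time column step (%.6g s) inconsistent with fs = %g Hz (>1%%)",
      median(dt), fs), class = "hrv_format_error")
  }
  ecg_record(mat[, 2], fs = fs, t0 = mat[1, 1])
}

#' Write an ECG record to CSV
#'
#' Two-column `time,voltage` layout at full precision.
#'
#' @param ecg An [ecg_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(ecg, path) {
  validate_ecg_record(ecg)
  writeLines(c("time,voltage",
               paste(formatC(ecg$time, digits = 17, format = "g"),
                     formatC(ecg$voltage, digits = 17, format = "g"),
                     sep = ",")),
             path)
  invisible(path)
}

# ---- report serialization ------------------------------------------------

# Every report object knows how to render itself as a plain list (JSON) and
# as a flat tibble (CSV). The JSON document carries `report_type` plus a
# schema version so readers can dispatch.

report_type <- function(x) {
  cls <- intersect(class(x),
                   c("hrv_time_report", "hrv_spectrum", "hrv_poincare",
                     "hrv_rqa", "hrv_embedding", "group_comparison",
                     "hrv_cohort_table"))
  if (length(cls)) cls[1] else "table"
}

report_payload <- function(x) {
  if (is.data.frame(x)) {
    list(report_type = report_type(x), schema_version = 1L,
         data = as.list(as.data.frame(x)))
  } else if (is.list(x)) {
    payload <- lapply(unclass(x), function(el) {
      if (is.data.frame(el)) as.list(as.data.frame(el)) else el
    })
    c(list(report_type = report_type(x), schema_version = 1L), payload)
  } else {
    stop_hrv("cannot serialize this object as a report")
  }
}

#' Write an analysis report to disk
#'
#' Serializes any hrvkit result bundle (time-domain, spectral, Poincaré,
#' recurrence, embedding, group comparison, or any tibble) as JSON (canonical,
#' full precision, `NA` stored as `null`) or flat CSV. JSON round-trips
#' through [read_report()] with all numeric fields bit-identical.
#'
#' @param report A result object or tibble.
#' @param path Output path.
#' @param format `"json"` (canonical) or `"csv"` (flat summary table).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report_payload(report), path,
                         auto_unbox = TRUE, digits = I(17), na = "null",
                         pretty = TRUE)
  } else {
    tab <- if (is.data.frame(report)) report else glance(report)
    utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#'
#' @param path Path to a JSON report.
#' @return A named list with the report fields (tabular fields as tibbles);
#'   `$report_type` names the originating result type.
#' @export
read_report <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  null_to_na <- function(el) {
    if (is.null(el)) return(NA)
    if (is.list(el) && !is.data.frame(el)) return(lapply(el, null_to_na))
    el
  }
  obj <- lapply(obj, null_to_na)
  if (identical(obj$report_type, "table") || !is.null(obj$data)) {
    obj$data <- tibble::as_tibble(obj$data)
  }
  obj
}
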