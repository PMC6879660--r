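#' Logger CSV dialects
#'
#' Describes how to parse a logger export: column names, datetime format
#' and decimal separator. Dialects can be written in YAML and loaded with
#' [read_dialect()]. The built-in `"ibutton"` dialect covers
#' timestamp/degC two-column exports; `"hobo"` covers timestamp plus one
#' or more value columns (e.g. lux and temperature); `"simple"` is the
#' package's own `time,value` format.
#'
#' @param time_col Name of the timestamp column.
#' @param value_cols Named character vector mapping output column names to
#'   input column names (a single unnamed value is mapped to `value`).
#' @param datetime_format `strptime` format, or `""` to let readr guess
#'   ISO-8601.
#' @param decimal_mark `"."` or `","`.
#' @param delim Field separator.
#' @return A `logger_dialect` list.
#' @export
logger_dialect <- function(time_col = "time", value_cols = c(value = "value"),
                           datetime_format = "", decimal_mark = ".",
                           delim = ",") {
  if (is.null(names(value_cols))) names(value_cols) <- "value"
  structure(list(time_col = time_col, value_cols = value_cols,
                 datetime_format = datetime_format,
                 decimal_mark = decimal_mark, delim = delim),
            class = "logger_dialect")
}

#' @rdname logger_dialect
#' @param path YAML file with the dialect fields.
#' @export
read_dialect <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(logger_dialect, list(
    time_col = y$time_col %||% "time",
    value_cols = unlist(y$value_cols) %||% c(value = "value"),
    datetime_format = y$datetime_format %||% "",
    decimal_mark = y$decimal_mark %||% ".",
    delim = y$delim %||% ","
  ))
}

#' Read a raw logger CSV
#'
#' Parses a logger export into the raw-sample tibble consumed by
#' [resample_to_grid()]: a `time` column plus one column per recorded
#' value.
#'
#' @param path CSV file.
#' @param dialect A [logger_dialect()] (or YAML path accepted by
#'   [read_dialect()]).
#' @return Tibble with `time` (POSIXct, UTC) and the mapped value columns.
#' @export
read_logger_csv <- function(path, dialect = logger_dialect()) {
  if (is.character(dialect)) dialect <- read_dialect(dialect)
  loc <- readr::locale(decimal_mark = dialect$decimal_mark, tz = "UTC")
  df <- readr::read_delim(path, delim = dialect$delim, locale = loc,
                          show_col_types = FALSE)
  tt <- df[[dialect$time_col]]
  if (!inherits(tt, "POSIXct")) {
    tt <- if (nzchar(dialect$datetime_format)) {
      readr::parse_datetime(as.character(tt), dialect$datetime_format,
                            locale = loc)
    } else {
      readr::parse_datetime(as.character(tt), locale = loc)
    }
  }
  out <- tibble::tibble(time = lubridate::with_tz(tt, "UTC"))
  for (nm in names(dialect$value_cols)) {
    out[[nm]] <- as.numeric(df[[dialect$value_cols[[nm]]]])
  }
  out
}

#' Read a sleep/sensor-off diary CSV
#'
#' Strict format: columns `subject_id`, `type` (`sleep`, `nap`,
#' `sensor_off`), `start`, `end` as ISO-8601 datetimes.
#'
#' @param path CSV file.
#' @return Diary tibble.
#' @export
read_diary_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        locale = readr::locale(tz = "UTC"))
  stopifnot(all(c("subject_id", "type", "start", "end") %in% names(df)))
  df$start <- lubridate::as_datetime(df$start, tz = "UTC")
  df$end <- lubridate::as_datetime(df$end, tz = "UTC")
  bad <- df$end <= df$start
  if (any(bad)) stop("diary interval with end <= start at row ",
                     which(bad)[1L], call. = FALSE)
  df
}

#' Write / read the canonical per-subject long-format channel CSV
#'
#' The canonical exchange format: one row per subject, variable and epoch
#' (`subject_id`, `variable`, `epoch_start`, `value`, `valid`).
#'
#' @param channels Channel-series tibble (or bind of several) with a
#'   `subject_id` column, or a named list of channel series plus
#'   `subject_id =` argument.
#' @param path Output CSV.
#' @param subject_id Subject identifier when `channels` is a list.
#' @return `write_channel_csv()` returns `path` invisibly;
#'   `read_channel_csv()` returns the long tibble.
#' @export
write_channel_csv <- function(channels, path, subject_id = NULL) {
  if (is.list(channels) && !is.data.frame(channels)) {
    channels <- dplyr::bind_rows(channels)
  }
  if (!"subject_id" %in% names(channels)) {
    channels <- dplyr::mutate(channels, subject_id = subject_id %||% "S01",
                              .before = 1L)
  }
  out <- dplyr::select(channels, "subject_id", "variable",
                       epoch_start = "time", "value", "valid")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_channel_csv
#' @export
read_channel_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        locale = readr::locale(tz = "UTC"))
  dplyr::rename(df, time = "epoch_start")
}

#' Write a recording as logger-dialect CSVs plus a diary CSV
#'
#' Emits the exact inputs the readers consume: one `time,value` CSV per
#' channel (10-min grid) and the diary, so synthetic cohorts can exercise
#' the full read path.
#'
#' @param rec An `acm_recording`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_recording_csv <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(rec$channels)) {
    ch <- rec$channels[[nm]]
    readr::write_csv(
      tibble::tibble(time = ch$time,
                     value = ifelse(ch$valid, ch$value, NA_real_)),
      file.path(dir, paste0(rec$subject_id, "_", nm, ".csv"))
    )
  }
  readr::write_csv(rec$diary, file.path(dir, paste0(rec$subject_id,
                                                    "_diary.csv")))
  invisible(dir)
}

#' Read a recording back from logger-dialect CSVs
#'
#' Counterpart of [write_recording_csv()]: reads each channel CSV through
#' [read_logger_csv()] and re-grids it with [resample_to_grid()], and
#' parses the diary.
#'
#' @param dir Directory written by [write_recording_csv()].
#' @param subject_id Subject identifier (file prefix).
#' @param site Site solar times (list with `sunset`, `sunrise`).
#' @return An `acm_recording`.
#' @export
read_recording_csv <- function(dir, subject_id,
                               site = list(sunset = "17:47",
                                           sunrise = "08:07")) {
  vars <- c("WT", "A", "P", "L", "ET")
  channels <- list()
  for (nm in vars) {
    f <- file.path(dir, paste0(subject_id, "_", nm, ".csv"))
    if (!file.exists(f)) next
    raw <- read_logger_csv(f)
    raw <- raw[!is.na(raw$value), , drop = FALSE]
    channels[[nm]] <- resample_to_grid(raw, nm,
                                       if (nm == "A") "sum" else "mean")
  }
  diary <- read_diary_csv(file.path(dir, paste0(subject_id, "_diary.csv")))
  structure(list(subject_id = subject_id, channels = channels,
                 diary = diary, site = site, truth = NULL),
            class = "acm_recording")
}

#' Write an analysis results bundle
#'
#' Persists the tidy results CSV (one row per subject and variable), the
#' chronotype assignments CSV, the agreement matrix as JSON, the
#' per-subject light-exposure table, the filter report and the exclusion
#' log.
#'
#' @param analysis An `acm_analysis`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_results <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tidy(analysis), file.path(dir, "indexes.csv"))
  readr::write_csv(analysis$sleep, file.path(dir, "sleep_timing.csv"))
  if (!is.null(analysis$assignments)) {
    readr::write_csv(analysis$assignments,
                     file.path(dir, "assignments.csv"))
  }
  if (!is.null(analysis$agreement)) {
    jsonlite::write_json(
      list(counts = as.data.frame(analysis$agreement$counts),
           summary = analysis$agreement$summary),
      file.path(dir, "agreement.json"), auto_unbox = TRUE, digits = NA
    )
  }
  if (nrow(analysis$light_bins %||% tibble::tibble())) {
    readr::write_csv(analysis$light_bins, file.path(dir, "light_bins.csv"))
  }
  jsonlite::write_json(analysis$filtered, file.path(dir, "filter_report.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(analysis$excluded, file.path(dir, "excluded.csv"))
  invisible(dir)
}
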