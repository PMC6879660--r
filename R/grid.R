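#' Channel series on the canonical 10-min epoch grid
#'
#' A *channel series* is a tibble with columns `variable` (character code:
#' `"WT"`, `"A"`, `"P"`, `"L"`, `"ET"`, `"TAP"` or `"S"`), `time` (POSIXct
#' epoch start, local clock kept in UTC), `value` (numeric) and `valid`
#' (logical mask). Epochs are half-open, left-labelled intervals anchored to
#' clock decades: the 08:00 epoch covers 08:00:00-08:09:59.9. All analysis
#' functions in the package consume and produce this shape.
#'
#' @param variable Channel code.
#' @param start POSIXct (or coercible) start of the first epoch.
#' @param values Numeric epoch values.
#' @param valid Logical mask, recycled; defaults to `!is.na(values)`.
#' @param epoch_minutes Epoch length in minutes (canonically 10).
#' @return A channel-series tibble.
#' @export
channel_series <- function(variable, start, values, valid = NULL,
                           epoch_minutes = 10) {
  start <- lubridate::as_datetime(start, tz = "UTC")
  if (is.null(valid)) valid <- !is.na(values)
  valid <- rep_len(valid, length(values)) & !is.na(values)
  tibble::tibble(
    variable = as.character(variable),
    time = start + lubridate::dminutes(epoch_minutes * (seq_along(values) - 1)),
    value = as.numeric(values),
    valid = valid
  )
}

#' Epoch-of-day slot index
#'
#' Maps a time to its slot of day: slot 0 is 00:00-00:10, slot 143 is
#' 23:50-24:00 on the canonical 10-min grid.
#'
#' @param time POSIXct vector.
#' @param epoch_minutes Epoch length in minutes.
#' @return Integer slot indices in `0:(1440 / epoch_minutes - 1)`.
#' @export
epoch_slot <- function(time, epoch_minutes = 10) {
  mins <- lubridate::hour(time) * 60 + lubridate::minute(time)
  as.integer(mins %/% epoch_minutes)
}

n_slots <- function(epoch_minutes = 10) as.integer(1440 %/% epoch_minutes)

#' Resample a raw logger stream to the canonical epoch grid
#'
#' Aggregates timestamped raw samples into uniform clock-anchored epochs
#' (mean for temperature, position and light; sum for the accumulated
#' activity counts). Epochs not fully covered by the raw stream at either
#' end are dropped; interior epochs with no samples are kept but invalid.
#'
#' @param raw Data frame with columns `time` (POSIXct or coercible) and
#'   `value` (numeric), time-sorted without duplicate timestamps.
#' @param variable Channel code for the output series.
#' @param method `"mean"` (WT, P, L, ET) or `"sum"` (activity).
#' @param epoch_minutes Target epoch length in minutes.
#' @return A channel-series tibble on the uniform grid.
#' @examples
#' raw <- tibble::tibble(
#'   time = lubridate::ymd_hms("2019-11-25 08:00:00") + 30 * (0:19),
#'   value = 3
#' )
#' resample_to_grid(raw, "A", method = "sum")  # one epoch of 60
#' @export
resample_to_grid <- function(raw, variable,
                             method = c("mean", "sum"), epoch_minutes = 10) {
  method <- match.arg(method)
  stopifnot(all(c("time", "value") %in% names(raw)))
  t <- lubridate::as_datetime(raw$time, tz = "UTC")
  if (length(t) < 2L) stop("need at least two raw samples", call. = FALSE)
  dt <- as.numeric(diff(t), units = "secs")
  if (any(dt < 0)) {
    stop("raw samples not time-sorted at ",
         format(t[which(dt < 0)[1L] + 1L]), call. = FALSE)
  }
  if (any(dt == 0)) {
    stop("duplicate timestamp at ",
         format(t[which(dt == 0)[1L]]), call. = FALSE)
  }
  step <- stats::median(dt)
  ep_sec <- epoch_minutes * 60
  t0 <- as.numeric(t[[1L]])
  t_end <- as.numeric(t[[length(t)]]) + step  # coverage is half-open per sample
  first_epoch <- ceiling(t0 / ep_sec) * ep_sec
  last_epoch <- floor(t_end / ep_sec) * ep_sec - ep_sec
  if (last_epoch < first_epoch) {
    stop("raw stream does not cover a single complete epoch", call. = FALSE)
  }
  starts <- seq(first_epoch, last_epoch, by = ep_sec)
  idx <- findInterval(as.numeric(t), starts + ep_sec) + 1L  # epoch membership
  keep <- as.numeric(t) >= first_epoch & idx <= length(starts)
  agg <- if (method == "sum") {
    tapply(raw$value[keep], idx[keep], sum)
  } else {
    tapply(raw$value[keep], idx[keep], mean)
  }
  values <- rep(NA_real_, length(starts))
  values[as.integer(names(agg))] <- as.numeric(agg)
  channel_series(variable,
                 lubridate::as_datetime(first_epoch, tz = "UTC"),
                 values, epoch_minutes = epoch_minutes)
}

# number of distinct calendar dates fully covered by the series grid
complete_days <- function(series, epoch_minutes = 10) {
  per_day <- n_slots(epoch_minutes)
  counts <- table(lubridate::as_date(series$time))
  sum(counts == per_day)
}

#' Mean daily waveform of a channel series
#'
#' Averages valid epochs by epoch-of-day slot across the recorded days,
#' producing the individual 24-h mean profile (144 slots on the 10-min
#' grid). Requires at least 7 complete days unless `toy_mode = TRUE`.
#'
#' @param series A channel-series tibble.
#' @param epoch_minutes Epoch length in minutes.
#' @param toy_mode Relax the 7-complete-days precondition (testing only).
#' @return Tibble with columns `variable`, `slot`, `tod` (minutes since
#'   midnight of the slot start), `value` (slot mean; `NA` where no valid
#'   epoch contributes), `n` (contributing epochs) and `sem` (across days).
#'   The attribute `incomplete` is `TRUE` when any slot has `n = 0`.
#' @export
mean_waveform <- function(series, epoch_minutes = 10, toy_mode = FALSE) {
  if (!toy_mode && complete_days(series, epoch_minutes) < 7L) {
    stop("fewer than 7 complete days recorded; variable excluded",
         call. = FALSE)
  }
  p <- n_slots(epoch_minutes)
  slot <- epoch_slot(series$time, epoch_minutes)
  ok <- series$valid & !is.na(series$value)
  wf <- tibble::tibble(slot = 0:(p - 1)) |>
    dplyr::left_join(
      tibble::tibble(slot = slot[ok], value = series$value[ok]) |>
        dplyr::group_by(.data$slot) |>
        dplyr::summarise(
          m = mean(.data$value),
          n = dplyr::n(),
          sem = stats::sd(.data$value) / sqrt(dplyr::n()),
          .groups = "drop"
        ),
      by = "slot"
    ) |>
    dplyr::mutate(
      variable = series$variable[[1L]],
      tod = .data$slot * epoch_minutes,
      n = dplyr::coalesce(.data$n, 0L)
    ) |>
    dplyr::select("variable", "slot", "tod", value = "m", "n", "sem")
  attr(wf, "incomplete") <- any(wf$n == 0L)
  wf
}

#' Group-average waveform across subjects
#'
#' Slot-wise mean of individual mean waveforms of one variable (e.g. per
#' chronotype group), with the standard error across subjects retained for
#' plotting.
#'
#' @param waveforms Tibble stacking individual waveforms (as produced by
#'   [mean_waveform()]) with an identifying `subject_id` column, all of the
#'   same `variable`.
#' @return Tibble with `variable`, `slot`, `tod`, `value`, `n`, `sem`.
#' @export
group_waveform <- function(waveforms) {
  if (is.null(waveforms) || nrow(waveforms) == 0L) {
    stop("no waveforms to average", call. = FALSE)
  }
  if (length(unique(waveforms$variable)) != 1L) {
    stop("group_waveform() requires a single variable", call. = FALSE)
  }
  waveforms |>
    dplyr::group_by(.data$variable, .data$slot, .data$tod) |>
    dplyr::summarise(
      m = mean(.data$value, na.rm = TRUE),
      n = sum(!is.na(.data$value)),
      sem = stats::sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
      .groups = "drop"
    ) |>
    dplyr::rename(value = "m") |>
    dplyr::arrange(.data$slot)
}
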