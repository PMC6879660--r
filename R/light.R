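#' Time in light-intensity bins by daytime interval
#'
#' Classifies every valid raw-lux epoch into one of four intensity bins -
#' very low (`[0, 10)` lux), low (`[10, 100)`), indoors bright
#' (`[100, 1000)`) and outdoors bright (`[1000, Inf)`) - within three
#' 8-h daytime intervals: morning (epochs 08:00-15:50), evening
#' (16:00-23:50) and night (00:00-07:50). Each valid epoch contributes its
#' full epoch length to exactly one cell; cells are averaged over the
#' recorded days and reported in minutes per day.
#'
#' Bin edges are half-open and lower-inclusive, matching the epoch
#' convention. The input must be raw lux, not the log-transformed series.
#'
#' @param light A cleaned light channel-series tibble in raw lux.
#' @param epoch_minutes Epoch length in minutes.
#' @return Tibble with one row per interval x bin: `interval`, `bin`,
#'   `minutes_per_day`, plus the number of days averaged over in the
#'   attribute `n_days`.
#' @export
light_time_in_bins <- function(light, epoch_minutes = 10) {
  x <- light$value[light$valid]
  if (length(x) && max(x, na.rm = TRUE) < 10) {
    stop("light series looks log-transformed (max < 10 lux); ",
         "time-in-bin analysis needs raw lux", call. = FALSE)
  }
  bins <- c("<10", "10-100", "100-1000", ">1000")
  intervals <- c("night", "morning", "evening")  # 00:00-, 08:00-, 16:00-
  n_days <- length(unique(lubridate::as_date(light$time)))
  df <- light |>
    dplyr::filter(.data$valid, !is.na(.data$value)) |>
    dplyr::mutate(
      interval = intervals[
        1L + (epoch_slot(.data$time, epoch_minutes) %/%
                (480L %/% epoch_minutes))],
      bin = bins[findInterval(.data$value, c(10, 100, 1000)) + 1L]
    ) |>
    dplyr::count(.data$interval, .data$bin) |>
    dplyr::mutate(minutes_per_day = .data$n * epoch_minutes / n_days)
  out <- tidyr::expand_grid(
    interval = factor(intervals[c(2, 3, 1)], levels = intervals[c(2, 3, 1)]),
    bin = factor(bins, levels = bins)
  ) |>
    dplyr::left_join(
      df |> dplyr::select("interval", "bin", "minutes_per_day") |>
        dplyr::mutate(interval = factor(.data$interval,
                                        levels = intervals[c(2, 3, 1)]),
                      bin = factor(.data$bin, levels = bins)),
      by = c("interval", "bin")
    ) |>
    dplyr::mutate(minutes_per_day = dplyr::coalesce(.data$minutes_per_day, 0))
  attr(out, "n_days") <- n_days
  out
}
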