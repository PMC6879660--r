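#' Mask sensor-off or manually flagged intervals
#'
#' Invalidates every epoch whose half-open span overlaps any of the given
#' intervals (typically sensor removals reported in the sleep diary).
#' Values are never modified, only the validity mask.
#'
#' @param series A channel-series tibble.
#' @param intervals Data frame with POSIXct (or coercible) columns `start`
#'   and `end`; an empty frame is the identity.
#' @param epoch_minutes Epoch length in minutes.
#' @return The series with overlapping epochs marked invalid.
#' @export
mask_intervals <- function(series, intervals, epoch_minutes = 10) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(series)
  s <- lubridate::as_datetime(intervals$start, tz = "UTC")
  e <- lubridate::as_datetime(intervals$end, tz = "UTC")
  if (any(e <= s)) stop("interval end must be after start", call. = FALSE)
  ep_start <- series$time
  ep_end <- series$time + lubridate::dminutes(epoch_minutes)
  hit <- rep(FALSE, nrow(series))
  for (k in seq_along(s)) {
    hit <- hit | (ep_start < e[[k]] & ep_end > s[[k]])
  }
  series$valid <- series$valid & !hit
  series
}

#' Interquartile-distance rate-of-change outlier filter
#'
#' Removes atypical points whose rate of change with respect to the previous
#' valid value exceeds the interquartile distance (IQD = Q3 - Q1, type-7
#' quantiles) of the series. A single pass: differences
#' `d_i = |x_i - x_{i-1}|` are taken over consecutive valid epochs (gaps
#' bridged), and epoch `i` is invalidated where `d_i > IQD`. By default the
#' IQD is computed on the valid values themselves; `on = "diffs"` computes
#' it on the differences instead.
#'
#' @param series A channel-series tibble.
#' @param on Distribution the IQD threshold is computed on: `"values"`
#'   (default) or `"diffs"`.
#' @return The filtered series; values untouched, mask updated. A constant
#'   series (IQD = 0) is returned unchanged with a warning.
#' @export
iqd_filter <- function(series, on = c("values", "diffs")) {
  on <- match.arg(on)
  idx <- which(series$valid & !is.na(series$value))
  if (length(idx) < 8L) stop("need at least 8 valid epochs", call. = FALSE)
  x <- series$value[idx]
  d <- abs(diff(x))
  ref <- if (on == "values") x else d
  q <- stats::quantile(ref, c(0.25, 0.75), type = 7, names = FALSE)
  iqd <- q[[2L]] - q[[1L]]
  if (iqd == 0) {
    warning("IQD is zero (constant distribution); no points removed",
            call. = FALSE)
    return(series)
  }
  drop <- idx[-1L][d > iqd]
  series$valid[drop] <- FALSE
  series
}

#' Logarithmic transform for light exposure
#'
#' Converts raw lux into logarithmic units, `log10(lux + 1)`, so 0 lux maps
#' to 0 and 999 lux to 3. Time-in-bin analysis always uses raw lux; this
#' transform feeds the waveform and non-parametric index computations.
#'
#' @param series A light (`L`) channel-series tibble in raw lux.
#' @return The series with values on the `log10(lux + 1)` scale.
#' @export
log_transform_light <- function(series) {
  if (any(series$value < 0, na.rm = TRUE)) {
    stop("negative lux values are not allowed", call. = FALSE)
  }
  series$value <- log10(series$value + 1)
  series
}
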