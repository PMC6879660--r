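#' Binary sleep series from a diary
#'
#' Converts diary intervals into the binary sleep channel S on the epoch
#' grid: an epoch scores 1 when its midpoint falls inside any declared
#' sleep or nap interval (intervals taken as `(start, end]`, so an
#' interval ending exactly on a midpoint still claims that epoch), 0
#' otherwise. Sensor-off intervals do not
#' contribute (they mask other channels instead; see [mask_intervals()]).
#'
#' @param diary Data frame with columns `type` (`"sleep"`, `"nap"`,
#'   `"sensor_off"`) and POSIXct (or coercible) `start`, `end`.
#' @param times POSIXct epoch-start vector defining the grid, or a
#'   channel-series tibble whose `time` column is used.
#' @param epoch_minutes Epoch length in minutes.
#' @return A channel-series tibble with `variable = "S"`, values 0/1.
#' @export
binarize_sleep <- function(diary, times, epoch_minutes = 10) {
  if (is.data.frame(times)) times <- times$time
  mid <- times + lubridate::dminutes(epoch_minutes / 2)
  asleep <- rep(FALSE, length(mid))
  keep <- diary$type %in% c("sleep", "nap")
  s <- lubridate::as_datetime(diary$start[keep], tz = "UTC")
  e <- lubridate::as_datetime(diary$end[keep], tz = "UTC")
  for (k in seq_along(s)) {
    asleep <- asleep | (mid > s[[k]] & mid <= e[[k]])
  }
  tibble::tibble(variable = "S", time = times,
                 value = as.numeric(asleep), valid = TRUE)
}

#' Cohort sleep probability waveform
#'
#' Percentage of subjects asleep at each epoch of day: the slot-wise mean
#' of the individual binary sleep profiles, expressed in percent.
#'
#' @param s_series Tibble stacking the subjects' S channel series, with a
#'   `subject_id` column.
#' @param epoch_minutes Epoch length in minutes.
#' @return A waveform tibble (`variable = "S"`, `value` in percent).
#' @export
sleep_probability <- function(s_series, epoch_minutes = 10) {
  if (is.null(s_series) || nrow(s_series) == 0L) {
    stop("empty cohort", call. = FALSE)
  }
  per_subject <- s_series |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(~ mean_waveform(.x, epoch_minutes, toy_mode = TRUE)) |>
    dplyr::ungroup()
  wf <- group_waveform(per_subject)
  wf$value <- wf$value * 100
  wf$sem <- wf$sem * 100
  wf
}

onset_class <- function(date) {
  # onset day-of-week lists: Sun-Thu work, Fri-Sat free
  wd <- lubridate::wday(date)  # 1 = Sunday
  ifelse(wd %in% c(1, 2, 3, 4, 5), "work", "free")
}

offset_class <- function(date) {
  # offset day-of-week lists: Mon-Fri work, Sat-Sun free
  wd <- lubridate::wday(date)
  ifelse(wd %in% 2:6, "work", "free")
}

#' Sleep timing, corrected midsleep on free days (MSFsc) and social jetlag
#'
#' From the diary's nocturnal sleep episodes (naps excluded), computes
#' circular-mean sleep onset and offset for work and free days, sleep
#' durations, midsleep on work days (MSW) and free days (MSF), the weekly
#' sleep-debt-corrected MSFsc and social jetlag (SJL). Day classes follow
#' the questionnaire convention: onsets on Sunday-Thursday are work nights
#' (Friday-Saturday free); offsets on Monday-Friday are work mornings
#' (Saturday-Sunday free). The correction
#' `MSFsc = MSF - (SD_f - SD_week)/2` (with `SD_week = (5 SD_w + 2 SD_f)/7`)
#' is applied only when free-day sleep exceeds work-day sleep; SJL is the
#' absolute circular difference between MSF and MSW in hours.
#'
#' @param diary Diary data frame (see [binarize_sleep()]); only rows with
#'   `type == "sleep"` are used.
#' @return One-row tibble: circular-mean clock times `onset_work`,
#'   `offset_work`, `onset_free`, `offset_free`, `MSW`, `MSF`, `MSFsc`
#'   (minutes since midnight), durations `SD_w`, `SD_f`, `SD_week` (hours),
#'   `SJL` (hours) and `n_work`/`n_free` night counts. Subjects with fewer
#'   than 3 work or 1 free night are flagged (`sufficient = FALSE`) with NA
#'   timing.
#' @export
sleep_timing <- function(diary) {
  ep <- diary[diary$type == "sleep", , drop = FALSE]
  na_row <- tibble::tibble(
    onset_work = NA_real_, offset_work = NA_real_,
    onset_free = NA_real_, offset_free = NA_real_,
    SD_w = NA_real_, SD_f = NA_real_, SD_week = NA_real_,
    MSW = NA_real_, MSF = NA_real_, MSFsc = NA_real_, SJL = NA_real_,
    n_work = 0L, n_free = 0L, sufficient = FALSE
  )
  if (nrow(ep) == 0L) return(na_row)
  s <- lubridate::as_datetime(ep$start, tz = "UTC")
  e <- lubridate::as_datetime(ep$end, tz = "UTC")
  on_min <- lubridate::hour(s) * 60 + lubridate::minute(s) +
    lubridate::second(s) / 60
  off_min <- lubridate::hour(e) * 60 + lubridate::minute(e) +
    lubridate::second(e) / 60
  on_cls <- onset_class(lubridate::as_date(s))
  off_cls <- offset_class(lubridate::as_date(e))
  n_work <- min(sum(on_cls == "work"), sum(off_cls == "work"))
  n_free <- min(sum(on_cls == "free"), sum(off_cls == "free"))
  if (n_work < 3L || n_free < 1L) {
    na_row$n_work <- n_work; na_row$n_free <- n_free
    return(na_row)
  }
  onset_w <- clock_mean(on_min[on_cls == "work"])
  onset_f <- clock_mean(on_min[on_cls == "free"])
  offset_w <- clock_mean(off_min[off_cls == "work"])
  offset_f <- clock_mean(off_min[off_cls == "free"])
  sd_w <- ((offset_w - onset_w) %% 1440) / 60
  sd_f <- ((offset_f - onset_f) %% 1440) / 60
  msw <- clock_wrap(onset_w + sd_w * 30)  # half the duration, in minutes
  msf <- clock_wrap(onset_f + sd_f * 30)
  sd_week <- (5 * sd_w + 2 * sd_f) / 7
  msfsc <- if (sd_f > sd_w) clock_wrap(msf - (sd_f - sd_week) * 30) else msf
  tibble::tibble(
    onset_work = onset_w, offset_work = offset_w,
    onset_free = onset_f, offset_free = offset_f,
    SD_w = sd_w, SD_f = sd_f, SD_week = sd_week,
    MSW = msw, MSF = msf, MSFsc = msfsc,
    SJL = social_jetlag(msw, msf),
    n_work = n_work, n_free = n_free, sufficient = TRUE
  )
}

#' Social jetlag
#'
#' Absolute circular difference between midsleep on work days and free
#' days, in hours (at most 12).
#'
#' @param MSW,MSF Midsleep clock times in minutes since midnight.
#' @return SJL in hours.
#' @export
social_jetlag <- function(MSW, MSF) {
  clock_dist(MSF, MSW) / 60
}
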