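#' Parameters for one synthetic subject
#'
#' Controls of the phenomenological week-long recording generator. The
#' defaults describe a young adult monitored for 7 days in winter:
#' mid-sleep around 04:00 shifted by the chronotype `phase_offset`, 8 h of
#' sleep, a wrist-temperature bump of 3 degC peaking at mid-sleep,
#' moderate day-to-day phase jitter (controls IS), channel noise (controls
#' IV), a 1-h weekend delay (controls SJL) and about one sensor removal
#' per week logged in the diary.
#'
#' @param subject_id Subject identifier.
#' @param phase_offset Chronotype phase shift in hours (negative = early).
#' @param sleep_duration Nightly sleep duration in hours, in (4, 12).
#' @param day_jitter_sd SD of the nightly phase jitter, hours.
#' @param weekend_delay Delay of the two weekend nights, hours.
#' @param wt_amplitude Wrist-temperature nocturnal bump, degC.
#' @param wt_noise_sd,a_noise,p_noise_sd,et_noise_sd,light_sdlog Channel
#'   noise levels (degC, relative activity scale, degrees, degC, log-lux).
#' @param light_gradient Change in log-mean daytime lux per hour of
#'   `phase_offset` (negative: earlier chronotypes see brighter days).
#' @param sensor_off_rate Expected sensor removals per week.
#' @param diary_noise_sd SD of diary-reported onset/offset error, minutes.
#' @param seed Integer seed for this subject's draws.
#' @return A `subject_params` list.
#' @export
subject_params <- function(subject_id = "S01",
                           phase_offset = 0,
                           sleep_duration = 8,
                           day_jitter_sd = 0.35,
                           weekend_delay = 1,
                           wt_amplitude = 3,
                           wt_noise_sd = 0.3,
                           a_noise = 1,
                           p_noise_sd = 8,
                           et_noise_sd = 0.4,
                           light_sdlog = 1.0,
                           light_gradient = -0.25,
                           sensor_off_rate = 1,
                           diary_noise_sd = 5,
                           seed = 1L) {
  stopifnot(sleep_duration > 4, sleep_duration < 12,
            day_jitter_sd >= 0, wt_noise_sd >= 0, p_noise_sd >= 0,
            et_noise_sd >= 0, light_sdlog >= 0, diary_noise_sd >= 0,
            sensor_off_rate >= 0)
  structure(as.list(environment()), class = "subject_params")
}

# squared-cosine bump of half-width w minutes around each center
bump <- function(t_min, centers, w = 300) {
  out <- numeric(length(t_min))
  for (cc in centers) {
    d <- abs(t_min - cc)
    hit <- d < w
    out[hit] <- pmax(out[hit], cos(pi * d[hit] / (2 * w))^2)
  }
  out
}

in_any <- function(t_min, starts, ends) {
  out <- rep(FALSE, length(t_min))
  for (k in seq_along(starts)) {
    out <- out | (t_min >= starts[[k]] & t_min < ends[[k]])
  }
  out
}

#' Generate one synthetic subject recording
#'
#' Simulates the five raw logger streams at their native sampling rates
#' (wrist temperature every 10 min; activity and signed position angle
#' every 30 s; light and environmental temperature every 10 min) for a
#' 7-day week starting on a Monday, together with the sleep diary
#' (programmed sleep plus reporting noise, and any sensor-off intervals)
#' and the ground truth. The raw streams are then aggregated onto the
#' canonical grid through [resample_to_grid()], exactly as recordings read
#' from disk would be.
#'
#' Construction: nightly mid-sleep is 04:00 + `phase_offset`, jittered
#' night-to-night and delayed on the two weekend nights; wrist temperature
#' is a wake baseline plus a squared-cosine nocturnal bump peaking at each
#' mid-sleep; activity and position are wake-gated positive signals;
#' light is near-dark during sleep and log-normal during wake, brighter
#' for earlier chronotypes; environmental temperature is a 24-h sinusoid.
#' During sensor-off intervals the wrist sensor reads near-ambient values,
#' emulating removal.
#'
#' @param params A [subject_params()] list.
#' @param start_date Date of the first recorded day (a Monday by default).
#' @param keep_raw Keep the raw streams in the result (memory-heavy).
#' @return An `acm_recording`: list with `subject_id`, `channels` (named
#'   list of channel-series tibbles on the 10-min grid; position already as
#'   absolute angle), `diary`, `site`, `truth` (programmed class inputs,
#'   realized nightly mid-sleeps and their circular mean `true_npm`), and
#'   optionally `raw`.
#' @export
simulate_subject <- function(params, start_date = "2019-11-25",
                             keep_raw = FALSE) {
  stopifnot(inherits(params, "subject_params"))
  set.seed(params$seed)
  start <- lubridate::as_datetime(paste(start_date, "00:00:00"), tz = "UTC")
  week_min <- 7 * 1440
  dur <- params$sleep_duration * 60

  # nightly mid-sleep in absolute minutes from week start (early hours of
  # each recorded day; weekend = nights waking Saturday / Sunday)
  base_mid <- 240 + params$phase_offset * 60
  jitter <- stats::rnorm(7, 0, params$day_jitter_sd * 60)
  # recorded days start Monday; weekend-delayed nights are those waking
  # Saturday (day 6) and Sunday (day 7)
  mid_abs <- (0:6) * 1440 + base_mid + jitter +
    c(rep(0, 5), rep(params$weekend_delay * 60, 2))
  sleep_start <- mid_abs - dur / 2
  sleep_end <- mid_abs + dur / 2
  # physiological nights continue beyond the recording edges (the night
  # before day 1 and the night after day 7), so the first and last days
  # carry the same evening/pre-dawn signal shape as interior days
  edge_jitter <- stats::rnorm(2, 0, params$day_jitter_sd * 60)
  mid_phys <- c(-1440 + base_mid + edge_jitter[[1L]], mid_abs,
                7 * 1440 + base_mid + edge_jitter[[2L]])
  phys_start <- mid_phys - dur / 2
  phys_end <- mid_phys + dur / 2

  # sensor-off intervals
  n_off <- stats::rpois(1, params$sensor_off_rate)
  off_start <- sort(stats::runif(n_off, 0, week_min - 120))
  off_end <- off_start + stats::runif(n_off, 30, 90)

  t10 <- seq(0, week_min - 10, by = 10)       # 10-min sample times
  t30 <- seq(0, week_min - 0.5, by = 0.5)     # 30-s sample times
  asleep10 <- in_any(t10, phys_start, phys_end)
  asleep30 <- in_any(t30, phys_start, phys_end)
  off10 <- in_any(t10, off_start, off_end)

  # wrist temperature: wake baseline + nocturnal bump; near-ambient when off
  wt <- 31.5 + params$wt_amplitude * bump(t10, mid_phys) +
    stats::rnorm(length(t10), 0, params$wt_noise_sd)
  wt[off10] <- 25 + stats::rnorm(sum(off10), 0, 0.5)
  wt <- pmin(pmax(wt, 20), 40)

  # activity: wake-gated gamma movement (deg per 30-s sample), rare arousals
  a <- ifelse(asleep30,
              stats::rbinom(length(t30), 1, 0.04) *
                stats::rexp(length(t30), 1 / 2),
              stats::rgamma(length(t30), shape = 1.5,
                            scale = 6 * params$a_noise))

  # position: signed tilt angle; near-horizontal asleep, upright awake
  p_sign <- sample(c(-1, 1), length(t30), replace = TRUE)
  p <- ifelse(asleep30,
              p_sign * pmin(abs(stats::rnorm(length(t30), 8,
                                             params$p_noise_sd)), 90),
              pmin(pmax(stats::rnorm(length(t30), 55, params$p_noise_sd),
                        -90), 90))

  # light: near-dark asleep; day/evening log-normal lux while awake with
  # AR(1) persistence in log-space (lighting environments last a while),
  # brighter days for earlier chronotypes
  tod10 <- t10 %% 1440
  daytime <- tod10 >= parse_clock("08:07") & tod10 < parse_clock("17:47")
  meanlog_day <- log(150) + params$light_gradient * params$phase_offset
  mu_log <- ifelse(daytime, meanlog_day, log(30))
  sd_log <- ifelse(daytime, params$light_sdlog, 0.8 * params$light_sdlog)
  phi <- 0.85
  z <- stats::filter(stats::rnorm(length(t10), 0, sqrt(1 - phi^2)),
                     phi, method = "recursive")
  lux <- exp(mu_log + sd_log * as.numeric(z))
  lux[asleep10] <- stats::runif(sum(asleep10), 0, 1)

  # environmental temperature: 24-h sinusoid peaking mid-afternoon
  et <- 18 + 4 * cos(2 * pi * (t10 - 15.5 * 60) / 1440) +
    stats::rnorm(length(t10), 0, params$et_noise_sd)

  raw <- list(
    WT = tibble::tibble(time = start + lubridate::dminutes(t10), value = wt),
    A = tibble::tibble(time = start + lubridate::dminutes(t30), value = a),
    P = tibble::tibble(time = start + lubridate::dminutes(t30), value = p),
    L = tibble::tibble(time = start + lubridate::dminutes(t10), value = lux),
    ET = tibble::tibble(time = start + lubridate::dminutes(t10), value = et)
  )

  # diary: programmed sleep with reporting noise, plus sensor-off log
  rep_on <- sleep_start + stats::rnorm(7, 0, params$diary_noise_sd)
  rep_off <- sleep_end + stats::rnorm(7, 0, params$diary_noise_sd)
  rep_off <- pmax(rep_off, rep_on + 60)
  t_origin <- start
  diary <- dplyr::bind_rows(
    tibble::tibble(subject_id = params$subject_id, type = "sleep",
                   start = t_origin + lubridate::dminutes(rep_on),
                   end = t_origin + lubridate::dminutes(rep_off)),
    if (n_off > 0) tibble::tibble(
      subject_id = params$subject_id, type = "sensor_off",
      start = t_origin + lubridate::dminutes(off_start),
      end = t_origin + lubridate::dminutes(off_end)
    )
  )

  mid_clock <- clock_wrap(mid_abs)
  truth <- list(
    phase_offset = params$phase_offset,
    midsleep = mid_clock,
    true_npm = clock_mean(mid_clock),
    sleep_start = start + lubridate::dminutes(sleep_start),
    sleep_end = start + lubridate::dminutes(sleep_end),
    sleep_duration = params$sleep_duration
  )

  # onto the canonical grid, same path as disk-read recordings; position
  # becomes absolute deviation from horizontal before resampling
  p_abs <- raw$P
  p_abs$value <- abs(p_abs$value)
  channels <- list(
    WT = resample_to_grid(raw$WT, "WT", "mean"),
    A = resample_to_grid(raw$A, "A", "sum"),
    P = resample_to_grid(p_abs, "P", "mean"),
    L = resample_to_grid(raw$L, "L", "mean"),
    ET = resample_to_grid(raw$ET, "ET", "mean")
  )

  rec <- list(
    subject_id = params$subject_id,
    params = params,
    start = start,
    channels = channels,
    diary = diary,
    site = list(sunset = "17:47", sunrise = "08:07"),
    truth = truth
  )
  if (keep_raw) rec$raw <- raw
  structure(rec, class = "acm_recording")
}

#' Generate a synthetic cohort with chronotype structure
#'
#' Draws `n` subjects from an early/neither/late class mix (20/60/20 by
#' default, matching the percentile definition of the classes), assigns
#' class-dependent phase offsets (class means -1 h, 0, +1.2 h with a 0.4-h
#' within-class SD) and subject-level sleep durations, and simulates each
#' recording. All randomness derives from the single `seed` through
#' per-subject seeds, so cohorts are exactly reproducible.
#'
#' @param n Number of subjects (>= 5).
#' @param class_mix Proportions for E/N/L; converted to exact counts by
#'   largest remainder.
#' @param seed Root seed.
#' @param class_means Named phase-offset means (hours) per class.
#' @param class_sd Within-class phase SD, hours.
#' @param start_date First recorded day.
#' @param ... Further arguments passed to [subject_params()] to override
#'   generator defaults for every subject.
#' @return List of `acm_recording` objects; each carries its ground-truth
#'   class in `truth$class`.
#' @export
simulate_cohort <- function(n = 50, class_mix = c(E = 0.2, N = 0.6, L = 0.2),
                            seed = 1L,
                            class_means = c(E = -1, N = 0, L = 1.2),
                            class_sd = 0.4,
                            start_date = "2019-11-25", ...) {
  stopifnot(n >= 5, abs(sum(class_mix) - 1) < 1e-8)
  set.seed(seed)
  base <- floor(class_mix * n)
  rem <- class_mix * n - base
  extra <- utils::head(order(rem, decreasing = TRUE), n - sum(base))
  counts <- base
  counts[extra] <- counts[extra] + 1
  classes <- rep(names(class_mix), counts)
  subj_seed <- sample.int(.Machine$integer.max - 1L, n)
  phase <- class_means[classes] + stats::rnorm(n, 0, class_sd)
  sdur <- stats::rnorm(n, 8, 0.5)
  sdur <- pmin(pmax(sdur, 5), 11)
  purrr::map(seq_len(n), function(i) {
    p <- subject_params(
      subject_id = sprintf("S%03d", i),
      phase_offset = phase[[i]],
      sleep_duration = sdur[[i]],
      seed = subj_seed[[i]],
      ...
    )
    rec <- simulate_subject(p, start_date = start_date)
    rec$truth$class <- classes[[i]]
    rec
  })
}
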