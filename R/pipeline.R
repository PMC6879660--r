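#' Pipeline configuration
#'
#' Resolved settings for [acm_pipeline()]. Defaults reproduce the standard
#' analysis: strict 7-day rule, value-based IQD filter, midpoint phase
#' markers, strict 3-component TAP, per-subject 5th/95th normalization
#' bounds, and the study-site winter solar times.
#'
#' @param sunset,sunrise Site solar times (`"HH:MM"`).
#' @param marker_convention `"midpoint"` or `"onset"` phase markers.
#' @param iqd_on IQD filter threshold distribution, `"values"` or `"diffs"`.
#' @param toy_mode Relax the 7-day preconditions (testing only).
#' @param min_tap_components Valid components required per TAP epoch (3 =
#'   strict, 2 allows one missing channel).
#' @param norm_probs Percentile pair for TAP normalization bounds.
#' @param epoch_minutes Canonical epoch length in minutes.
#' @return An `acm_config` list.
#' @export
acm_config <- function(sunset = "17:47", sunrise = "08:07",
                       marker_convention = c("midpoint", "onset"),
                       iqd_on = c("values", "diffs"),
                       toy_mode = FALSE,
                       min_tap_components = 3,
                       norm_probs = c(0.05, 0.95),
                       epoch_minutes = 10) {
  structure(list(
    sunset = sunset, sunrise = sunrise,
    marker_convention = match.arg(marker_convention),
    iqd_on = match.arg(iqd_on),
    toy_mode = toy_mode,
    min_tap_components = min_tap_components,
    norm_probs = norm_probs,
    epoch_minutes = epoch_minutes
  ), class = "acm_config")
}

# clean one sensor channel: diary mask then IQD filter
clean_channel <- function(series, diary, config) {
  off <- diary[diary$type == "sensor_off", , drop = FALSE]
  series <- mask_intervals(series, off, config$epoch_minutes)
  n_before <- sum(series$valid)
  series <- suppressWarnings(iqd_filter(series, on = config$iqd_on))
  attr(series, "n_filtered") <- n_before - sum(series$valid)
  series
}

# per-subject stage: clean channels, build TAP and S, compute indexes
analyze_subject <- function(rec, config) {
  em <- config$epoch_minutes
  cleaned <- purrr::imap(rec$channels, function(ch, nm) {
    clean_channel(ch, rec$diary, config)
  })
  raw_light <- cleaned$L
  if (!is.null(cleaned$L)) cleaned$L <- log_transform_light(cleaned$L)

  nb <- function(ch) norm_bounds(ch, config$norm_probs)
  wt_b <- nb(cleaned$WT); a_b <- nb(cleaned$A); p_b <- nb(cleaned$P)
  wt_n <- normalize_channel(cleaned$WT, wt_b[1], wt_b[2], invert = TRUE)
  a_n <- normalize_channel(cleaned$A, a_b[1], a_b[2], invert = FALSE)
  p_n <- normalize_channel(cleaned$P, p_b[1], p_b[2], invert = FALSE)
  tap <- integrate_tap(wt_n, a_n, p_n,
                       min_components = config$min_tap_components)
  s <- binarize_sleep(rec$diary, cleaned$WT$time, em)

  analyzable <- c(cleaned[c("L", "ET", "WT", "A", "P")],
                  list(TAP = tap, S = s))
  rows <- purrr::imap(analyzable, function(ch, nm) {
    res <- tryCatch({
      idx <- nonparametric_indexes(ch, em, toy_mode = config$toy_mode)
      wf <- mean_waveform(ch, em, toy_mode = config$toy_mode)
      idx$NPM <- night_phase_marker(idx, config$marker_convention)
      idx$DPM <- day_phase_marker(idx, config$marker_convention)
      list(idx = idx, wf = wf, error = NA_character_)
    }, error = function(e) list(idx = NULL, wf = NULL,
                                error = conditionMessage(e)))
    res
  })
  list(
    subject_id = rec$subject_id,
    indexes = dplyr::bind_rows(purrr::map(rows, "idx")) |>
      dplyr::mutate(subject_id = rec$subject_id, .before = 1L),
    waveforms = dplyr::bind_rows(purrr::compact(purrr::map(rows, "wf"))) |>
      dplyr::mutate(subject_id = rec$subject_id, .before = 1L),
    failures = tibble::tibble(
      subject_id = rec$subject_id,
      variable = names(rows),
      error = purrr::map_chr(rows, "error")
    ) |> dplyr::filter(!is.na(.data$error)),
    filtered = tibble::tibble(
      subject_id = rec$subject_id,
      variable = names(cleaned),
      n_filtered = purrr::map_int(cleaned, ~ attr(.x, "n_filtered") %||% 0L)
    ),
    light_bins = tryCatch(
      light_time_in_bins(raw_light, em) |>
        dplyr::mutate(subject_id = rec$subject_id, .before = 1L),
      error = function(e) NULL
    ),
    sleep = sleep_timing(rec$diary) |>
      dplyr::mutate(subject_id = rec$subject_id, .before = 1L),
    s_series = dplyr::mutate(s, subject_id = rec$subject_id, .before = 1L),
    truth = rec$truth
  )
}

#' Run the full ACM analysis pipeline on a cohort
#'
#' Orchestrates the per-subject stages - diary-based masking, IQD outlier
#' filtering, light log transform, TAP integration, binary sleep, mean
#' waveforms, non-parametric indexes and phase markers - then the
#' cohort-level stages: NRA rescaling per variable, CFI, DM-NPM against the
#' site darkness center, CHI, sleep probability, MSFsc/SJL, chronotype
#' classification from the TAP NPM and its agreement with the MSFsc-based
#' classification. Per-subject failures are quarantined and reported, not
#' fatal.
#'
#' @param recordings List of `acm_recording` objects (see
#'   [simulate_subject()] or [read_recording_csv()]).
#' @param config An [acm_config()].
#' @return An `acm_analysis` object: list with `indexes` (tidy
#'   subject-by-variable tibble with IS, IV, M/L levels and onsets, RA,
#'   NRA, CFI, NPM, DPM, DM_NPM, CHI), `waveforms`, `sleep` (per-subject
#'   timing incl. MSFsc and SJL), `sleep_probability`, `light_bins`,
#'   `assignments`, `agreement`, `excluded`, `filtered` and `config`.
#' @export
acm_pipeline <- function(recordings, config = acm_config()) {
  per <- purrr::map(recordings, function(rec) {
    tryCatch(analyze_subject(rec, config),
             error = function(e) list(subject_id = rec$subject_id,
                                      fatal = conditionMessage(e)))
  })
  fatal <- purrr::keep(per, ~ !is.null(.x$fatal))
  per <- purrr::keep(per, ~ is.null(.x$fatal))
  if (length(per) == 0L) stop("all subjects failed", call. = FALSE)

  indexes <- dplyr::bind_rows(purrr::map(per, "indexes"))
  center <- darkness_center(config$sunset, config$sunrise)
  indexes <- indexes |>
    dplyr::group_by(.data$variable) |>
    dplyr::mutate(NRA = safe_nra(.data$RA)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      CFI = circadian_function_index(.data$IS, .data$IV, .data$NRA),
      DM_NPM = dm_npm(.data$NPM, center),
      CHI = circadian_health_index(.data$NRA, .data$IS, .data$DM_NPM)
    )

  sleep <- dplyr::bind_rows(purrr::map(per, "sleep"))
  s_all <- dplyr::bind_rows(purrr::map(per, "s_series"))

  tap_npm <- indexes |>
    dplyr::filter(.data$variable == "TAP", !is.na(.data$NPM)) |>
    dplyr::select("subject_id", npm = "NPM")
  assignments <- NULL
  agreement <- NULL
  if (nrow(tap_npm) >= 5L) {
    acm_cls <- classify_by_npm(tap_npm)
    msf <- sleep |>
      dplyr::filter(.data$sufficient) |>
      dplyr::select("subject_id", "MSFsc")
    assignments <- acm_cls |>
      dplyr::rename(tap_npm = "npm", acm_class = "class") |>
      dplyr::select("subject_id", "tap_npm", "acm_class") |>
      dplyr::left_join(msf, by = "subject_id")
    both <- assignments |> dplyr::filter(!is.na(.data$MSFsc))
    if (nrow(both) >= 5L) {
      msf_cls <- classify_by_msfsc(both)
      assignments <- assignments |>
        dplyr::left_join(
          dplyr::select(msf_cls, "subject_id", msf_class = "class"),
          by = "subject_id"
        )
      paired <- assignments |>
        dplyr::filter(!is.na(.data$acm_class), !is.na(.data$msf_class))
      agreement <- chronotype_agreement(paired$acm_class, paired$msf_class)
    }
  }

  structure(list(
    indexes = indexes,
    waveforms = dplyr::bind_rows(purrr::map(per, "waveforms")),
    sleep = sleep,
    sleep_probability = sleep_probability(s_all, config$epoch_minutes),
    light_bins = dplyr::bind_rows(purrr::compact(purrr::map(per, "light_bins"))),
    assignments = assignments,
    agreement = agreement,
    excluded = dplyr::bind_rows(
      purrr::map(per, "failures"),
      tibble::tibble(
        subject_id = purrr::map_chr(fatal, "subject_id"),
        variable = NA_character_,
        error = purrr::map_chr(fatal, "fatal")
      )
    ),
    filtered = dplyr::bind_rows(purrr::map(per, "filtered")),
    truth = purrr::map(per, "truth") |>
      rlang::set_names(purrr::map_chr(per, "subject_id")),
    darkness_center = center,
    config = config
  ), class = "acm_analysis")
}

#' @export
print.acm_analysis <- function(x, ...) {
  n <- length(unique(x$indexes$subject_id))
  cat("<acm_analysis> ", n, " subjects, ",
      length(unique(x$indexes$variable)), " variables\n", sep = "")
  if (!is.null(x$agreement)) {
    s <- x$agreement$summary
    cat(sprintf("chronotype agreement: %.1f%% coincidence, %.1f%% one-step, %.1f%% opposite\n",
                s$coincidence_pct, s$one_step_pct, s$opposite_pct))
  }
  if (nrow(x$excluded)) {
    cat(nrow(x$excluded), "subject-variable exclusions (see $excluded)\n")
  }
  invisible(x)
}

#' Tidy the per-subject circadian summary
#'
#' One row per subject and variable, with the full index set.
#'
#' @param x An `acm_analysis`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.acm_analysis <- function(x, ...) {
  out <- x$indexes
  if (!is.null(x$assignments)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(x$assignments, "subject_id", "acm_class"),
      by = "subject_id"
    )
  }
  out
}

#' Cohort-level one-row summary
#'
#' @param x An `acm_analysis`.
#' @param ... Unused.
#' @return A one-row tibble with subject counts, mean TAP indexes, mean
#'   MSFsc/SJL and the chronotype agreement percentages.
#' @export
glance.acm_analysis <- function(x, ...) {
  tap <- dplyr::filter(x$indexes, .data$variable == "TAP")
  ok <- dplyr::filter(x$sleep, .data$sufficient)
  tibble::tibble(
    n_subjects = length(unique(x$indexes$subject_id)),
    n_excluded = nrow(x$excluded),
    IS_TAP = mean(tap$IS, na.rm = TRUE),
    IV_TAP = mean(tap$IV, na.rm = TRUE),
    RA_TAP = mean(tap$RA, na.rm = TRUE),
    CFI_TAP = mean(tap$CFI, na.rm = TRUE),
    CHI_TAP = mean(tap$CHI, na.rm = TRUE),
    NPM_TAP = clock_mean(tap$NPM),
    MSFsc = clock_mean(ok$MSFsc),
    SJL = mean(ok$SJL, na.rm = TRUE),
    coincidence_pct = if (!is.null(x$agreement))
      x$agreement$summary$coincidence_pct else NA_real_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

`%||%` <- function(a, b) if (is.null(a)) b else a

# cohort NRA that degrades to NA (e.g. a degenerate RA distribution such
# as binary sleep, where every subject has RA = 1) instead of failing
safe_nra <- function(ra) {
  tryCatch(suppressWarnings(normalize_ra_cohort(ra)),
           error = function(e) rep(NA_real_, length(ra)))
}
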