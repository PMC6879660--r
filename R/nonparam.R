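#' Window lengths for the most/least active hours by variable
#'
#' Day-active variables (light, environmental temperature, activity,
#' position, TAP) use M10/L5; wrist temperature and sleep, whose acrophase
#' falls in the rest period, use M5/L10.
#'
#' @param variable Channel code.
#' @return Named numeric `c(m_hours, l_hours)`.
#' @export
ml_hours <- function(variable) {
  if (variable %in% c("WT", "S")) c(m_hours = 5, l_hours = 10)
  else c(m_hours = 10, l_hours = 5)
}

check_np_pre <- function(series, epoch_minutes, toy_mode) {
  if (toy_mode) return(invisible(TRUE))
  if (complete_days(series, epoch_minutes) < 7L) {
    stop("fewer than 7 complete days", call. = FALSE)
  }
  if (mean(series$valid) < 0.8) {
    stop("fewer than 80% valid epochs", call. = FALSE)
  }
  invisible(TRUE)
}

#' Interdaily stability (IS)
#'
#' Constancy of the 24-h pattern across days: the ratio of the variance of
#' the mean daily profile to the total variance,
#' `IS = (N * sum_h (xbar_h - xbar)^2) / (p * sum_i (x_i - xbar)^2)`, with
#' `h` over the `p` epoch-of-day slots (144 on the 10-min grid) and `i` over
#' all `N` valid epochs. 1 means perfectly repeated days; i.i.d. noise gives
#' values near `p/N`.
#'
#' @param series A channel-series tibble.
#' @param epoch_minutes Epoch length in minutes.
#' @param toy_mode Relax the 7-day / 80%-valid preconditions.
#' @return IS, clamped to `[0, 1]`.
#' @export
interdaily_stability <- function(series, epoch_minutes = 10,
                                 toy_mode = FALSE) {
  check_np_pre(series, epoch_minutes, toy_mode)
  ok <- series$valid & !is.na(series$value)
  x <- series$value[ok]
  slot <- epoch_slot(series$time, epoch_minutes)[ok]
  N <- length(x)
  xbar <- mean(x)
  tot <- sum((x - xbar)^2)
  if (tot == 0) stop("zero total variance; IS undefined", call. = FALSE)
  hbar <- tapply(x, slot, mean)
  p <- n_slots(epoch_minutes)
  is_val <- (N * sum((hbar - xbar)^2)) / (p * tot)
  min(max(is_val, 0), 1)
}

#' Intradaily variability (IV)
#'
#' Rhythm fragmentation: the normalized mean square of successive
#' differences, `IV = (N * sum d_i^2) / (m * sum (x_i - xbar)^2)` with the
#' `m` differences taken over adjacent valid epoch pairs only (for a fully
#' valid series `m = N - 1`, the classical form). About 0 for a smooth
#' sinusoid, about 2 for white noise, larger for ultradian alternation.
#'
#' @inheritParams interdaily_stability
#' @return IV (non-negative, not clamped).
#' @export
intradaily_variability <- function(series, epoch_minutes = 10,
                                   toy_mode = FALSE) {
  check_np_pre(series, epoch_minutes, toy_mode)
  ok <- series$valid & !is.na(series$value)
  x <- series$value[ok]
  pos <- which(ok)
  adjacent <- diff(pos) == 1L
  d <- diff(x)[adjacent]
  if (length(d) == 0L) stop("no adjacent valid epoch pairs", call. = FALSE)
  N <- length(x)
  tot <- sum((x - mean(x))^2)
  if (tot == 0) stop("zero variance; IV undefined", call. = FALSE)
  (N * sum(d^2)) / (length(d) * tot)
}

# circular window means over all starts for a 144-slot waveform
window_means <- function(values, w) {
  p <- length(values)
  cs <- cumsum(c(0, values, values))
  (cs[(1:p) + w] - cs[1:p]) / w
}

pick_extreme <- function(wm, max. = TRUE) {
  target <- if (max.) max(wm) else min(wm)
  tol <- 1e-9 * max(1, abs(target))
  hit <- if (max.) which(wm >= target - tol) else which(wm <= target + tol)
  hit[[1L]]  # earliest onset on ties
}

#' Most- and least-active window levels (M10/L5 or M5/L10)
#'
#' Exhaustive circular search over all 144 window starts of the mean daily
#' waveform for the `m_hours` consecutive hours with the highest mean (M)
#' and the `l_hours` consecutive hours with the lowest mean (L), wrapping
#' midnight. Ties are broken to the earliest onset after 00:00.
#'
#' @param waveform A complete waveform tibble from [mean_waveform()].
#' @param m_hours,l_hours Window lengths in hours; defaults follow
#'   [ml_hours()] for the waveform's variable.
#' @param epoch_minutes Epoch length in minutes.
#' @return One-row tibble: `variable`, `m_hours`, `l_hours`, `M_level`,
#'   `M_onset`, `L_level`, `L_onset` (onsets in minutes since midnight).
#' @export
ml_levels <- function(waveform, m_hours = NULL, l_hours = NULL,
                      epoch_minutes = 10) {
  variable <- waveform$variable[[1L]]
  if (is.null(m_hours) || is.null(l_hours)) {
    h <- ml_hours(variable)
    if (is.null(m_hours)) m_hours <- h[["m_hours"]]
    if (is.null(l_hours)) l_hours <- h[["l_hours"]]
  }
  v <- waveform$value[order(waveform$slot)]
  if (anyNA(v)) stop("incomplete waveform (empty slots)", call. = FALSE)
  spm <- 60 / epoch_minutes
  wm_m <- window_means(v, as.integer(m_hours * spm))
  wm_l <- window_means(v, as.integer(l_hours * spm))
  i_m <- pick_extreme(wm_m, max. = TRUE)
  i_l <- pick_extreme(wm_l, max. = FALSE)
  tibble::tibble(
    variable = variable, m_hours = m_hours, l_hours = l_hours,
    M_level = wm_m[[i_m]], M_onset = (i_m - 1) * epoch_minutes,
    L_level = wm_l[[i_l]], L_onset = (i_l - 1) * epoch_minutes
  )
}

#' Relative amplitude (RA)
#'
#' Day-night contrast: `(M - L) / (M + L)` from the most- and least-active
#' window levels. In `[0, 1]` for non-negative levels.
#'
#' @param M_level,L_level Window mean levels, `M >= L`, `M + L > 0`.
#' @return RA.
#' @export
relative_amplitude <- function(M_level, L_level) {
  if (any(M_level + L_level <= 0)) {
    stop("M + L must be positive for RA", call. = FALSE)
  }
  if (any(M_level < L_level)) stop("M must be >= L", call. = FALSE)
  (M_level - L_level) / (M_level + L_level)
}

#' Cohort-normalized relative amplitude (NRA)
#'
#' Rescales the cohort's RA distribution for one variable so that the
#' highest and lowest 5% of values are recoded to 1 and 0 and the rest are
#' linearly rescaled between them:
#' `NRA = clamp((RA - p5) / (p95 - p5), 0, 1)` with type-7 percentiles.
#'
#' @param ra Per-subject RA values for one variable across the cohort.
#' @return NRA values in `[0, 1]`, parallel to `ra`.
#' @export
normalize_ra_cohort <- function(ra) {
  ok <- !is.na(ra)
  if (sum(ok) < 20L) {
    warning("fewer than 20 subjects; NRA percentiles are unstable",
            call. = FALSE)
  }
  q <- stats::quantile(ra[ok], c(0.05, 0.95), type = 7, names = FALSE)
  if (q[[1L]] == q[[2L]]) {
    stop("degenerate cohort RA distribution (p5 = p95)", call. = FALSE)
  }
  pmin(pmax((ra - q[[1L]]) / (q[[2L]] - q[[1L]]), 0), 1)
}

#' Circadian function index (CFI)
#'
#' Average of three rhythm-quality components, each on `[0, 1]`: interdaily
#' stability, inverted-rescaled intradaily variability (`1 - min(IV, 2)/2`),
#' and the cohort-normalized relative amplitude.
#'
#' @param IS,IV,NRA Component indexes (vectorized).
#' @return CFI in `[0, 1]`.
#' @export
circadian_function_index <- function(IS, IV, NRA) {
  stopifnot(all(IS >= 0 & IS <= 1, na.rm = TRUE),
            all(IV >= 0, na.rm = TRUE),
            all(NRA >= 0 & NRA <= 1, na.rm = TRUE))
  (IS + (1 - pmin(IV, 2) / 2) + NRA) / 3
}

#' Per-subject non-parametric index set for one channel
#'
#' Convenience wrapper computing IS, IV, the M/L window levels and onsets,
#' and RA for a cleaned channel series. NRA and CFI are cohort-level
#' quantities added downstream (see [acm_pipeline()]).
#'
#' @inheritParams interdaily_stability
#' @return One-row tibble: `variable`, `IS`, `IV`, `m_hours`, `l_hours`,
#'   `M_level`, `M_onset`, `L_level`, `L_onset`, `RA`.
#' @export
nonparametric_indexes <- function(series, epoch_minutes = 10,
                                  toy_mode = FALSE) {
  wf <- mean_waveform(series, epoch_minutes, toy_mode = toy_mode)
  ml <- ml_levels(wf, epoch_minutes = epoch_minutes)
  dplyr::mutate(
    ml,
    IS = interdaily_stability(series, epoch_minutes, toy_mode),
    IV = intradaily_variability(series, epoch_minutes, toy_mode),
    RA = relative_amplitude(.data$M_level, .data$L_level),
    .after = "variable"
  )
}
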