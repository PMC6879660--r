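#' Night and day phase markers
#'
#' The night phase marker (NPM) is the timing of the 5-h window that falls
#' in the rest period: L5 for day-active variables (L, ET, A, P, TAP) and
#' M5 for wrist temperature and sleep. The day phase marker (DPM) is the
#' complementary 10-h window (M10, or L10 for WT and sleep). Both are
#' reported as the circular midpoint of the window by default; the onset
#' convention is available via `convention = "onset"`.
#'
#' @param ml One-row tibble from [ml_levels()] computed with the
#'   variable-appropriate window lengths.
#' @param convention `"midpoint"` (default) or `"onset"`.
#' @return Clock time in minutes since midnight.
#' @export
night_phase_marker <- function(ml, convention = c("midpoint", "onset")) {
  convention <- match.arg(convention)
  night_hours <- 5
  rest_peaker <- ml$variable[[1L]] %in% c("WT", "S")
  if (rest_peaker) {
    if (ml$m_hours[[1L]] != night_hours) {
      stop("NPM for ", ml$variable[[1L]], " needs an M5 window", call. = FALSE)
    }
    onset <- ml$M_onset[[1L]]
  } else {
    if (ml$l_hours[[1L]] != night_hours) {
      stop("NPM for ", ml$variable[[1L]], " needs an L5 window", call. = FALSE)
    }
    onset <- ml$L_onset[[1L]]
  }
  if (convention == "onset") return(clock_wrap(onset))
  clock_midpoint(onset, onset + night_hours * 60)
}

#' @rdname night_phase_marker
#' @export
day_phase_marker <- function(ml, convention = c("midpoint", "onset")) {
  convention <- match.arg(convention)
  day_hours <- 10
  rest_peaker <- ml$variable[[1L]] %in% c("WT", "S")
  if (rest_peaker) {
    if (ml$l_hours[[1L]] != day_hours) {
      stop("DPM for ", ml$variable[[1L]], " needs an L10 window", call. = FALSE)
    }
    onset <- ml$L_onset[[1L]]
  } else {
    if (ml$m_hours[[1L]] != day_hours) {
      stop("DPM for ", ml$variable[[1L]], " needs an M10 window", call. = FALSE)
    }
    onset <- ml$M_onset[[1L]]
  }
  if (convention == "onset") return(clock_wrap(onset))
  clock_midpoint(onset, onset + day_hours * 60)
}

#' Center of natural darkness
#'
#' Circular midpoint of the night span from sunset to the next sunrise, the
#' solar reference phase against which night phase markers are compared.
#' The defaults are the study-site winter values (Murcia, late
#' November-December; midpoints of the printed sunrise/sunset ranges) and
#' should be overridden per site and season.
#'
#' @param sunset,sunrise Clock times (`"HH:MM"` or minutes since midnight).
#' @return Darkness center in minutes since midnight.
#' @examples
#' format_clock(darkness_center("17:47", "08:07"))  # "00:57"
#' @export
darkness_center <- function(sunset = "17:47", sunrise = "08:07") {
  ss <- parse_clock(sunset)
  sr <- parse_clock(sunrise)
  if (isTRUE(all.equal(ss, sr))) stop("sunset equals sunrise", call. = FALSE)
  clock_midpoint(ss, sr)
}

#' Difference from midnight for the night phase marker (DM-NPM)
#'
#' Shortest circular distance in hours between the NPM and the center of
#' natural darkness, divided by the maximum possible difference (12 h).
#' 0 means complete coincidence with the solar night; 1 means the marker is
#' 12 h out of phase.
#'
#' @param npm Night phase marker (minutes since midnight, vectorized).
#' @param center Darkness center (minutes since midnight).
#' @return DM-NPM in `[0, 1]`.
#' @export
dm_npm <- function(npm, center) {
  clock_dist(npm, center) / 60 / 12
}

#' Circadian Health Index (CHI)
#'
#' Integrates three characteristics of a healthy rhythm - day-night
#' contrast (NRA), day-to-day stability (IS) and synchronization to the
#' natural dark phase (inverted DM-NPM):
#' `CHI = (NRA + IS + (1 - DM_NPM)) / 3`. 1 describes a robust, stable
#' rhythm phased with the solar night; 0 a flat, unstable rhythm 12 h out
#' of phase.
#'
#' @param NRA,IS,DM_NPM Component indexes in `[0, 1]` (vectorized).
#' @return CHI in `[0, 1]`.
#' @export
circadian_health_index <- function(NRA, IS, DM_NPM) {
  inputs <- cbind(NRA, IS, DM_NPM)
  if (any(inputs < 0 | inputs > 1, na.rm = TRUE)) {
    stop("CHI components must lie in [0, 1]", call. = FALSE)
  }
  (NRA + IS + (1 - DM_NPM)) / 3
}
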