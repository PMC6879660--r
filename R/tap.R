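#' Per-subject normalization bounds for TAP components
#'
#' Robust bounds for mapping a cleaned channel onto `[0, 1]`: the 5th and
#' 95th percentiles (type-7) of the valid values over the recorded week.
#' Values outside the bounds are clamped, so the bulk of the data spans the
#' unit interval while residual spikes cannot stretch the scale.
#'
#' @param series A cleaned channel-series tibble.
#' @param probs Lower/upper percentile pair.
#' @return Named numeric `c(lo, hi)`.
#' @export
norm_bounds <- function(series, probs = c(0.05, 0.95)) {
  x <- series$value[series$valid & !is.na(series$value)]
  q <- stats::quantile(x, probs, type = 7, names = FALSE)
  c(lo = q[[1L]], hi = q[[2L]])
}

#' Normalize a channel to the unit interval
#'
#' Affine map `x -> clamp((x - lo) / (hi - lo), 0, 1)`, followed by
#' inversion `x -> 1 - x` for wrist temperature (which peaks during sleep,
#' opposite to activity and position).
#'
#' @param series A channel-series tibble.
#' @param lo,hi Values mapped to 0 and 1; defaults are the per-subject
#'   5th/95th percentiles from [norm_bounds()].
#' @param invert Invert after scaling; defaults to `TRUE` for `WT`.
#' @return The series with values in `[0, 1]`.
#' @export
normalize_channel <- function(series, lo = NULL, hi = NULL, invert = NULL) {
  if (is.null(lo) || is.null(hi)) {
    b <- norm_bounds(series)
    if (is.null(lo)) lo <- b[["lo"]]
    if (is.null(hi)) hi <- b[["hi"]]
  }
  if (is.null(invert)) invert <- series$variable[[1L]] == "WT"
  if (hi <= lo) {
    stop("degenerate normalization bounds for channel ",
         series$variable[[1L]], " (lo >= hi)", call. = FALSE)
  }
  z <- pmin(pmax((series$value - lo) / (hi - lo), 0), 1)
  if (invert) z <- 1 - z
  series$value <- z
  series
}

#' Integrate the TAP variable
#'
#' Averages the three normalized components - wrist temperature (inverted),
#' activity and position - epoch by epoch into the composite TAP series.
#' TAP is 0 at the fullest rest (lowest activity, horizontal position,
#' highest wrist temperature) and 1 at the fullest activation. By default an
#' epoch is valid only when all three components are valid; with
#' `min_components = 2` the mean of the available components is used when
#' one is missing.
#'
#' @param wt,a,p Normalized channel-series tibbles on the same grid
#'   (wrist temperature already inverted).
#' @param min_components Minimum valid components per epoch (3 = strict).
#' @return A channel-series tibble with `variable = "TAP"`.
#' @export
integrate_tap <- function(wt, a, p, min_components = 3) {
  if (nrow(wt) != nrow(a) || nrow(wt) != nrow(p) ||
      !all(wt$time == a$time) || !all(wt$time == p$time)) {
    stop("TAP components must share the same epoch grid", call. = FALSE)
  }
  comp <- cbind(wt$value, a$value, p$value)
  ok <- cbind(wt$valid, a$valid, p$valid) & !is.na(comp)
  n_ok <- rowSums(ok)
  comp[!ok] <- NA_real_
  val <- rowMeans(comp, na.rm = TRUE)
  val[n_ok == 0L] <- NA_real_
  tibble::tibble(
    variable = "TAP",
    time = wt$time,
    value = val,
    valid = n_ok >= min_components
  )
}
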