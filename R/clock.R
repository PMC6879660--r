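#' Circular clock-time arithmetic
#'
#' Clock times are represented internally as minutes since midnight on a
#' 24-h circle (`[0, 1440)` minutes). These helpers implement the circular
#' operations every phase computation in the package relies on: signed and
#' absolute differences, midpoints of (possibly midnight-wrapping) windows,
#' and circular means of a sample of clock times.
#'
#' @param x,y Clock times in minutes since midnight (numeric, vectorized).
#' @return Minutes since midnight in `[0, 1440)` for times, signed minutes in
#'   `(-720, 720]` for `clock_diff()`.
#' @name clock
NULL

#' @rdname clock
#' @export
clock_wrap <- function(x) x %% 1440

#' @rdname clock
#' @description `clock_diff()` is the signed shortest difference `x - y` on
#'   the circle, in minutes within `(-720, 720]`.
#' @export
clock_diff <- function(x, y) {
  d <- (x - y) %% 1440
  ifelse(d > 720, d - 1440, d)
}

#' @rdname clock
#' @description `clock_dist()` is the absolute circular distance in minutes,
#'   at most 720 (12 h).
#' @export
clock_dist <- function(x, y) abs(clock_diff(x, y))

#' @rdname clock
#' @param start,end Window boundaries in minutes since midnight; the window
#'   runs forward from `start` to `end`, wrapping midnight when `end < start`.
#' @description `clock_midpoint()` is the midpoint of the forward span from
#'   `start` to `end`.
#' @export
clock_midpoint <- function(start, end) {
  span <- (end - start) %% 1440
  clock_wrap(start + span / 2)
}

#' @rdname clock
#' @description `clock_mean()` is the circular mean of a sample of clock
#'   times (vector resultant direction); `NA` for an empty sample, and the
#'   first value when the resultant has zero length (antipodal degenerate
#'   case).
#' @export
clock_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  theta <- x / 1440 * 2 * pi
  s <- mean(sin(theta)); c <- mean(cos(theta))
  if (sqrt(s^2 + c^2) < 1e-12) return(x[[1L]])
  # round away sub-microsecond fp residue so means at midnight report 0,
  # not 1440 - epsilon
  clock_wrap(round(atan2(s, c) / (2 * pi) * 1440, 6))
}

#' Parse and format clock times
#'
#' `parse_clock()` converts `"HH:MM"` (optionally `"HH:MM:SS"`) strings to
#' minutes since midnight; `format_clock()` does the reverse, rounding to the
#' nearest minute.
#'
#' @param x Character vector of `"HH:MM"` times, or numeric minutes.
#' @return Numeric minutes since midnight, or character `"HH:MM"`.
#' @examples
#' parse_clock("04:30")
#' format_clock(1437.5)
#' @export
parse_clock <- function(x) {
  if (is.numeric(x)) return(clock_wrap(x))
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- suppressWarnings(as.numeric(p))
    if (length(p) < 2L || anyNA(p[1:2])) stop("cannot parse clock time", call. = FALSE)
    clock_wrap(p[[1L]] * 60 + p[[2L]] + if (length(p) >= 3L) p[[3L]] / 60 else 0)
  }, numeric(1))
}

#' @rdname parse_clock
#' @export
format_clock <- function(x) {
  m <- round(clock_wrap(x)) %% 1440
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}
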