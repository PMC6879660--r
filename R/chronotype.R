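#' Chronotype classification from the TAP night phase marker
#'
#' Objective early/neither/late classification by percentiles of the night
#' phase marker: subjects in the lowest (earliest) 20% are E-types, those
#' in the highest 20% L-types, and the remaining 60% N-types. Before
#' ranking, clock times are unwrapped onto a continuous axis centered on
#' the cohort circular mean, so a subject with an NPM just before midnight
#' ranks earlier than one at 04:00. Membership is by rank:
#' E for ranks `<= ceiling(0.2 n)`, L for ranks `> n - ceiling(0.2 n)`;
#' ties are broken by input order (with a warning when ties span a
#' boundary), and a zero-variance cohort is assigned all-N.
#'
#' @param df Data frame with a subject identifier column and the phase
#'   column named by `phase_col` (clock times in minutes since midnight,
#'   or `"HH:MM"` strings).
#' @param phase_col Name of the phase column (`"npm"` by default;
#'   [classify_by_msfsc()] uses `"MSFsc"`).
#' @param id_col Name of the subject identifier column.
#' @return The input tibble with columns `phase_unwrapped`, `rank` and
#'   `class` (factor E/N/L) appended; attributes `cut_early` and
#'   `cut_late` hold the resulting class-boundary clock times (minutes).
#' @export
classify_by_npm <- function(df, phase_col = "npm", id_col = "subject_id") {
  x <- parse_clock(df[[phase_col]])
  n <- length(x)
  if (n < 5L) stop("need at least 5 subjects to classify", call. = FALSE)
  mu <- clock_mean(x)
  unwrapped <- clock_diff(x, mu)  # deviation from cohort mean, (-720, 720]
  out <- tibble::as_tibble(df)
  out$phase_unwrapped <- clock_wrap(mu) + unwrapped
  if (max(unwrapped) == min(unwrapped)) {
    warning("all phase values identical; assigning every subject N",
            call. = FALSE)
    out$rank <- seq_len(n)
    out$class <- factor(rep("N", n), levels = c("E", "N", "L"))
    attr(out, "cut_early") <- NA_real_
    attr(out, "cut_late") <- NA_real_
    return(out)
  }
  rk <- order(order(unwrapped, seq_len(n)))  # ties by input order
  k <- ceiling(0.2 * n)
  cls <- rep("N", n)
  cls[rk <= k] <- "E"
  cls[rk > n - k] <- "L"
  srt <- sort(unwrapped)
  if ((srt[k] == srt[k + 1L]) || (srt[n - k] == srt[n - k + 1L])) {
    warning("ties span a percentile boundary; broken by input order",
            call. = FALSE)
  }
  out$rank <- rk
  out$class <- factor(cls, levels = c("E", "N", "L"))
  attr(out, "cut_early") <- clock_wrap(mu + srt[k])
  attr(out, "cut_late") <- clock_wrap(mu + srt[n - k])
  out
}

#' @rdname classify_by_npm
#' @export
classify_by_msfsc <- function(df, phase_col = "MSFsc",
                              id_col = "subject_id") {
  classify_by_npm(df, phase_col = phase_col, id_col = id_col)
}

#' Agreement between ACM- and questionnaire-based chronotypes
#'
#' Cross-tabulates the two E/N/L label vectors and summarises agreement as
#' the percentage of coincident labels, one-step disagreements (E or L
#' called N, or N called E or L) and opposite-category errors (E called L
#' or vice versa).
#'
#' @param acm,msf Parallel class vectors (factors or characters with
#'   levels E/N/L) for the same subjects, in the same order.
#' @return List with the 3x3 `counts` table (ACM rows, questionnaire
#'   columns) and a one-row `summary` tibble: `n`, `coincidence_pct`,
#'   `one_step_pct`, `opposite_pct`.
#' @export
chronotype_agreement <- function(acm, msf) {
  if (length(acm) != length(msf)) {
    stop("class vectors must describe the same subjects", call. = FALSE)
  }
  lv <- c("E", "N", "L")
  acm <- factor(as.character(acm), levels = lv)
  msf <- factor(as.character(msf), levels = lv)
  if (anyNA(acm) || anyNA(msf)) stop("unknown class labels", call. = FALSE)
  counts <- table(acm = acm, msf = msf)
  step <- abs(as.integer(acm) - as.integer(msf))
  n <- length(acm)
  list(
    counts = counts,
    summary = tibble::tibble(
      n = n,
      coincidence_pct = 100 * mean(step == 0L),
      one_step_pct = 100 * mean(step == 1L),
      opposite_pct = 100 * mean(step == 2L)
    )
  )
}
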