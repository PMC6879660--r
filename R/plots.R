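#' Plot mean daily waveforms with SEM bands
#'
#' Line plot of one or more 24-h mean waveforms (e.g. per chronotype
#' group), with a shaded mean +/- SEM ribbon where the `sem` column is
#' present.
#'
#' @param waveforms Waveform tibble (from [mean_waveform()],
#'   [group_waveform()] or `acm_analysis$waveforms`), optionally with a
#'   grouping column.
#' @param colour Name of the grouping column mapped to colour (e.g.
#'   `"subject_id"` or a class column), or `NULL`.
#' @return A ggplot object.
#' @export
plot_waveform <- function(waveforms, colour = NULL) {
  aes_args <- if (!is.null(colour)) {
    ggplot2::aes(x = .data$tod / 60, y = .data$value,
                 colour = .data[[colour]], fill = .data[[colour]],
                 group = .data[[colour]])
  } else {
    ggplot2::aes(x = .data$tod / 60, y = .data$value)
  }
  p <- ggplot2::ggplot(waveforms, aes_args)
  if ("sem" %in% names(waveforms) && any(!is.na(waveforms$sem))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$value - .data$sem,
                   ymax = .data$value + .data$sem),
      alpha = 0.25, colour = NA
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 4),
                                limits = c(0, 24),
                                expand = c(0, 0)) +
    ggplot2::labs(x = "Time of day (h)", y = "Level") +
    ggplot2::facet_wrap(ggplot2::vars(.data$variable), scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Tercile threshold for actogram marking
#'
#' The rest phase is marked using the variable-appropriate tercile of the
#' cleaned week: values at or above the third tercile (highest 33%) for
#' wrist temperature and sleep, values at or below the first tercile
#' (lowest 33%) for the day-active variables.
#'
#' @param series A cleaned channel-series tibble.
#' @return List with `threshold` and `side` (`"above"`/`"below"`).
#' @export
actogram_threshold <- function(series) {
  x <- series$value[series$valid & !is.na(series$value)]
  if (series$variable[[1L]] %in% c("WT", "S")) {
    list(threshold = stats::quantile(x, 2 / 3, type = 7, names = FALSE),
         side = "above")
  } else {
    list(threshold = stats::quantile(x, 1 / 3, type = 7, names = FALSE),
         side = "below")
  }
}

#' Double-plotted actogram
#'
#' Conventional chronobiology raster: one row per recorded day over a
#' 48-h axis (each day followed by the next), with epochs beyond the
#' variable-appropriate tercile threshold marked (the rest band). Invalid
#' epochs are left blank.
#'
#' @param series A cleaned channel-series tibble covering >= 7 days.
#' @param epoch_minutes Epoch length in minutes.
#' @return A ggplot object.
#' @export
plot_actogram <- function(series, epoch_minutes = 10) {
  thr <- actogram_threshold(series)
  marked <- if (thr$side == "above") series$value >= thr$threshold
            else series$value <= thr$threshold
  d0 <- min(lubridate::as_date(series$time))
  base <- tibble::tibble(
    day = as.integer(lubridate::as_date(series$time) - d0) + 1L,
    tod = (lubridate::hour(series$time) * 60 +
             lubridate::minute(series$time)) / 60,
    marked = marked & series$valid,
    valid = series$valid
  )
  doubled <- dplyr::bind_rows(
    base,
    dplyr::mutate(base, day = .data$day - 1L, tod = .data$tod + 24)
  ) |> dplyr::filter(.data$day >= 1L, .data$day <= max(base$day))
  ggplot2::ggplot(doubled,
                  ggplot2::aes(x = .data$tod, y = .data$day)) +
    ggplot2::geom_tile(
      data = ~ dplyr::filter(.x, .data$valid),
      ggplot2::aes(fill = .data$marked),
      width = epoch_minutes / 60, height = 0.9
    ) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey20",
                                          `FALSE` = "grey90"),
                               guide = "none") +
    ggplot2::scale_y_reverse(breaks = seq_len(max(base$day))) +
    ggplot2::scale_x_continuous(breaks = seq(0, 48, 6), expand = c(0, 0)) +
    ggplot2::labs(x = "Time (h, double-plotted)", y = "Day",
                  title = paste0(series$variable[[1L]], " actogram")) +
    ggplot2::theme_minimal()
}

#' Autoplot methods
#'
#' `autoplot()` on an `acm_analysis` draws the cohort group waveforms per
#' variable (mean +/- SEM across subjects).
#'
#' @param object An `acm_analysis`.
#' @param variables Variables to include.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.acm_analysis <- function(object,
                                  variables = unique(object$waveforms$variable),
                                  ...) {
  wf <- object$waveforms |>
    dplyr::filter(.data$variable %in% variables) |>
    dplyr::group_by(.data$variable, .data$slot, .data$tod) |>
    dplyr::summarise(
      sem = stats::sd(.data$value, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$value))),
      value = mean(.data$value, na.rm = TRUE),
      .groups = "drop"
    )
  plot_waveform(wf)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
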