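
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

session_breaks <- function(series) {
  b <- series |>
    dplyr::group_by(.data$session) |>
    dplyr::summarise(start = min(.data$center), .groups = "drop")
  b$start[-1]
}

#' Plot a sliding-window series
#'
#' Draws the per-participant series (thin lines) and, when several
#' participants are present, the cohort median (thick line), with dashed
#' vertical lines at session boundaries.
#'
#' @param object An `sb_window_series` from [sliding_series()] or
#'   [cohort_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sb_window_series <- function(object, ...) {
  statistic <- attr(object, "statistic") %||% "value"
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$center, y = .data$value))
  if ("participant" %in% names(df) && length(unique(df$participant)) > 1) {
    p <- p +
      ggplot2::geom_line(ggplot2::aes(group = .data$participant),
                         alpha = 0.35, linewidth = 0.3) +
      ggplot2::geom_line(data = tibble::as_tibble(cohort_median_series(object)),
                         linewidth = 0.9)
  } else {
    p <- p + ggplot2::geom_line(linewidth = 0.6)
  }
  p +
    ggplot2::geom_vline(xintercept = session_breaks(df), linetype = "dashed",
                        colour = "grey55", linewidth = 0.3) +
    ggplot2::labs(x = "trial (window centre)", y = statistic) +
    ggplot2::theme_minimal()
}

#' Deviation-versus-shift scatter with robust fits
#'
#' The per-condition behavioural signature plot: terminal deviation
#' against true shift in one dimension, one panel per condition, with the
#' robust bisquare fit overlaid. A flat line means feedback-driven
#' compensation; a unit slope means pure reliance on the prior mean.
#'
#' @param records Trial-record tibble of one participant.
#' @param dimension `"h"` or `"v"`.
#' @param sessions Optional session filter.
#' @return A ggplot object.
#' @export
plot_condition_slopes <- function(records, dimension = c("v", "h"),
                                  sessions = NULL) {
  dimension <- match.arg(dimension)
  cols <- dim_cols(dimension)
  recs <- dplyr::filter(records, .data$phase == "main")
  if (!is.null(sessions)) recs <- dplyr::filter(recs, .data$session %in% !!sessions)
  fits <- condition_slopes(recs, dimension, by_participant = FALSE)
  ggplot2::ggplot(recs, ggplot2::aes(x = .data[[cols$s]], y = .data[[cols$dev]])) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_abline(data = fits,
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept),
                         colour = "firebrick") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = sprintf("true shift s_%s (cm)", dimension),
                  y = sprintf("terminal deviation (cm), %s", dimension)) +
    ggplot2::theme_minimal()
}

#' Plot a reproduction run's learning curves
#'
#' Cohort-median series of one statistic for every simulated group,
#' overlaid.
#'
#' @param x An `sb_reproduction`.
#' @param statistic One of `"partial_slope"`, `"mean_h"`, `"mean_v"`,
#'   `"xy_corr"`.
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(x, statistic = c("partial_slope", "mean_h",
                                                  "mean_v", "xy_corr")) {
  statistic <- match.arg(statistic)
  df <- purrr::imap(x$analysis, function(an, g) {
    med <- an[[statistic]]$median %||% an[[statistic]]$series
    if (is.null(med)) return(NULL)
    dplyr::mutate(tibble::as_tibble(med), group = g)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$center, y = .data$value,
                                   colour = .data$group)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "window index", y = statistic, colour = "group") +
    ggplot2::theme_minimal()
}
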