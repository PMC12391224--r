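#' Plot per-well heat-flow traces by group
#'
#' One line per well, panelled by experimental group, with the group-mean
#' trace overlaid. Times are shown in hours; traces can be thinned for speed.
#'
#' @param x A [thermogram_set()].
#' @param every Keep every `every`-th time point (default thins 1 Hz traces
#'   to 1/min).
#' @return A ggplot object.
#' @export
plot_thermograms <- function(x, every = 60L) {
  stopifnot(inherits(x, "thermogram_set"))
  long <- as_tibble(x)
  keep_t <- x$time_s[seq(1, length(x$time_s), by = max(1L, as.integer(every)))]
  long <- dplyr::filter(long, .data$time_s %in% keep_t,
                        .data$role == "sample")
  means <- long |>
    dplyr::group_by(.data$group, .data$time_s) |>
    dplyr::summarise(power_uW = mean(.data$power_uW), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s / 3600,
                                     y = .data$power_uW)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$well_id),
                       linewidth = 0.2, alpha = 0.5) +
    ggplot2::geom_line(data = means, linewidth = 0.9, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::labs(x = "Time (h)", y = "Heat flow (µW)")
}

#' Stripchart of per-cell total heat with compact letters
#'
#' An enhanced stripchart of per-well values by group with the group mean,
#' its 95% confidence interval (normal approximation on the group's own
#' variance), and the compact letter display appended to the group label.
#'
#' @param data A heat table (e.g. [process_plate()] output or
#'   [chondrocyte_heats()]).
#' @param value,group Columns holding the response and group label.
#' @param cld Optional [compact_letters()] tibble; computed from a
#'   [heat_anova()] fit when `NULL`.
#' @return A ggplot object.
#' @export
plot_heat_strips <- function(data, value, group, cld = NULL) {
  df <- dplyr::transmute(data, value = {{ value }},
                         group = as.character({{ group }}))
  if (is.null(cld)) {
    cld <- heat_anova(df, .data$value, .data$group)$cld
  }
  df <- dplyr::left_join(df, cld, by = "group") |>
    dplyr::mutate(label = paste0(.data$group, " (", .data$letters, ")"))
  stats_df <- df |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      mean = mean(.data$value),
      half = stats::qt(0.975, dplyr::n() - 1) *
        stats::sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.8) +
    ggplot2::geom_pointrange(
      data = stats_df,
      ggplot2::aes(y = .data$mean, ymin = .data$mean - .data$half,
                   ymax = .data$mean + .data$half),
      colour = "red3", shape = 18, inherit.aes = TRUE
    ) +
    ggplot2::labs(x = NULL, y = "Total heat (µJ/cell)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.heat_anova <- function(object, ...) {
  est <- dplyr::left_join(tibble::as_tibble(object$estimates), object$cld,
                          by = "group") |>
    dplyr::mutate(
      half = stats::qt(0.975, .data$n - 1) *
        sqrt(.data$variance / .data$n),
      label = paste0(.data$group, " (", .data$letters, ")")
    )
  ggplot2::ggplot(est, ggplot2::aes(x = .data$label, y = .data$mean)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$half,
                   ymax = .data$mean + .data$half)
    ) +
    ggplot2::labs(x = NULL, y = "Group mean total heat (µJ/cell)")
}
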