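#' Plot an evaluation report
#'
#' Histograms of the per-sample cross-locus correlations and the per-locus
#' cross-sample correlations.
#'
#' @param object An `accessibility_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot accessibility_eval
#' @export
autoplot.accessibility_eval <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(statistic = "r_L (per sample)", value = object$r_l$r_l),
    tibble::tibble(statistic = "r_C (per locus)", value = object$r_c$r_c)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "Pearson correlation (prediction vs truth)", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity-rank curve
#'
#' @param object A `sensitivity_curve` tibble.
#' @param ... Further curves to overlay, named.
#' @return A ggplot object.
#' @method autoplot sensitivity_curve
#' @export
autoplot.sensitivity_curve <- function(object, ...) {
  extra <- list(...)
  df <- dplyr::bind_rows(c(list(method = object), extra), .id = "method")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$sensitivity,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "top N predicted sites", y = "sensitivity") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot motif activity along pseudotime
#'
#' @param object A tibble from [motif_activity()] with pseudotime columns.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_motif_activity <- function(object, ...) {
  stopifnot(all(c("pseudotime_rank", "activity", "lineage") %in% names(object)))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pseudotime_rank,
                                       y = .data$activity,
                                       colour = .data$lineage)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "pseudotime rank", y = "mean predicted accessibility") +
    ggplot2::theme_minimal()
}
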