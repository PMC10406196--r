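#' Plot per-template activation indexes
#'
#' Boxplots of the activation index by template (faceted by main-task
#' condition when several are present); for relative results, by contrast.
#'
#' @param object a `ctt_tracking`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot ctt_tracking
#' @export
autoplot.ctt_tracking <- function(object, ...) {
  df <- tibble::as_tibble(object)
  xcol <- if ("template" %in% names(df)) "template" else "contrast"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[xcol]], y = .data$value)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::labs(x = NULL, y = attr(object, "metric"),
                  title = "Template activation indexes") +
    ggplot2::theme_minimal()
  if (length(unique(df$condition)) > 1L) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$condition))
  }
  p
}

#' Plot a time-resolved statistic map
#'
#' @param object a `ctt_statmap` with time geometry.
#' @param ... unused.
#' @return A ggplot object (time course of the statistic).
#' @method autoplot ctt_statmap
#' @export
autoplot.ctt_statmap <- function(object, ...) {
  if (object$geometry$type != "time") {
    abort_ctt("autoplot supports time-resolved statistic maps; write volumes as NIfTI")
  }
  df <- tibble::tibble(time_bin = as.integer(names(object$values)),
                       value = unname(object$values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_bin, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time bin", y = object$statistic) +
    ggplot2::theme_minimal()
}

#' Plot a temporal-generalization matrix
#'
#' Heat map with localizer (template) bins on the y axis and main-task bins
#' on the x axis.
#'
#' @param object a `ctt_tgm`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot ctt_tgm
#' @export
autoplot.ctt_tgm <- function(object, ...) {
  df <- tibble::as_tibble(as.table(object$values), .name_repair = "minimal")
  names(df) <- c("localizer_bin", "main_bin", "value")
  df$localizer_bin <- as.integer(as.character(df$localizer_bin))
  df$main_bin <- as.integer(as.character(df$main_bin))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$main_bin, y = .data$localizer_bin,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "main-task time bin", y = "localizer time bin",
                  fill = object$statistic) +
    ggplot2::theme_minimal()
}

#' Plot a permutation null distribution
#'
#' Histogram of the permutation null for one unit with the observed
#' statistic marked.
#'
#' @param object a `ctt_permutation`.
#' @param unit which unit/column to show (default 1).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot ctt_permutation
#' @export
autoplot.ctt_permutation <- function(object, unit = 1L, ...) {
  df <- tibble::tibble(null = object$null[, unit])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey75", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed[unit],
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "null statistic",
                  title = sprintf("p = %.4g", object$p_values[unit])) +
    ggplot2::theme_minimal()
}
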