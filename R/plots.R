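#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a measure table: values by condition and measure
#'
#' Box-and-jitter plot of per-recording LZc and PCIst values across wake
#' and sedation conditions, one facet per measure (free y scales: the two
#' measures live on very different scales).
#'
#' @param object a `measure_table` ([as_measure_table()]).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.measure_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$condition <- factor(df$condition,
                         levels = c("wake_eo", "wake_ec",
                                    sort(unique(grep("^sedation", df$condition,
                                                     value = TRUE)))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "measure value",
                  title = "Complexity measures by condition") +
    ggplot2::theme_minimal()
}

#' Plot sedation measure values by experience class
#'
#' The within-sedation contrast the mixed models test: per-recording values
#' of each measure grouped by the three-class experience classification.
#'
#' @param tab a `measure_table`.
#' @return a ggplot object.
#' @export
plot_by_class <- function(tab) {
  df <- tibble::as_tibble(tab)
  df <- df[grepl("^sedation", df$condition) & !is.na(df$experience_class), ]
  df$experience_class <- factor(df$experience_class, levels = class_levels())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$experience_class, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18, size = 3,
                          colour = "red") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "experience class", y = "measure value",
                  title = "Sedation measures by experience classification") +
    ggplot2::theme_minimal()
}

#' @rdname pcist
#' @param object a `pcist_result`.
#' @export
autoplot.pcist_result <- function(object, ...) {
  ggplot2::ggplot(object$per_component,
                  ggplot2::aes(x = factor(.data$component), y = .data$dnst)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "principal component", y = expression(Delta * "NST"),
                  title = sprintf("PCIst = %.2f", object$value)) +
    ggplot2::theme_minimal()
}

#' @rdname time_resolved_lzc
#' @param object an `lzc_timecourse`.
#' @param ... unused.
#' @export
autoplot.lzc_timecourse <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$lzc)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "normalized LZc",
                  title = "Time-resolved Lempel-Ziv complexity") +
    ggplot2::theme_minimal()
}

#' @rdname tabulate_reports
#' @param object a `report_tabulation`.
#' @param ... unused.
#' @export
autoplot.report_tabulation <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$q1, variable = "Q1"),
    dplyr::mutate(object$q2, variable = "Q2"),
    dplyr::mutate(object$class, variable = "class")
  )
  df$category <- factor(df$category, levels = unique(df$category))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::facet_wrap(~variable, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "awakenings",
                  title = "Distribution of awakening reports") +
    ggplot2::theme_minimal()
}
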