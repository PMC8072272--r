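# ggplot2 views of the main result types.

#' Violin plot of per-locus dN/dS by gene class
#'
#' @param records Tibble with `omega` and a grouping column.
#' @param class_col Grouping column (default `"broad"`).
#' @return A ggplot object.
#' @export
plot_omega_by_class <- function(records, class_col = "broad") {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data[[class_col]], y = .data$omega)) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey40") +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 2) +
    ggplot2::labs(x = NULL, y = "dN/dS") +
    ggplot2::theme_minimal()
}

#' Mean dN/dS against breadth of expression
#'
#' @param records Tibble with `omega` and integer `breadth`.
#' @return A ggplot object.
#' @export
plot_breadth_omega <- function(records) {
  records |>
    dplyr::filter(.data$breadth >= 1) |>
    ggplot2::ggplot(ggplot2::aes(x = factor(.data$breadth), y = .data$omega)) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey40") +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 2) +
    ggplot2::labs(x = "tissues expressed in", y = "dN/dS") +
    ggplot2::theme_minimal()
}

#' Histogram of the bootstrap null with the observed difference
#'
#' @param object A `bootstrap_null` from [bootstrap_sc_si_null()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bootstrap_null <- function(object, ...) {
  ggplot2::ggplot(object$diffs, ggplot2::aes(x = .data$diff)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey80", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$ci95, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "SC - SI dN/dS difference (bootstrap replicates)",
                  y = "replicates") +
    ggplot2::theme_minimal()
}
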