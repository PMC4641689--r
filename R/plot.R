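# ggplot2 views of the main result types.

#' Heatmap of a pairwise identity matrix
#'
#' @param object An `identity_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.identity_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, fill = .data$identity_pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.0f", .data$identity_pct)), size = 3
    ) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), name = "identity %") +
    ggplot2::labs(x = NULL, y = NULL, title = "Pairwise identity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Sliding-window identity track
#'
#' Line plot of [sliding_window_identity()] output, the standard view of
#' where along a genome alignment two sequences diverge.
#'
#' @param windows A tibble from [sliding_window_identity()].
#' @return A ggplot object.
#' @export
plot_window_identity <- function(windows) {
  stopifnot(all(c("window_start", "identity_pct") %in% names(windows)))
  ggplot2::ggplot(windows, ggplot2::aes(.data$window_start, .data$identity_pct)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(
      x = "alignment position (window start)", y = "identity (%)",
      title = "Sliding-window identity"
    ) +
    ggplot2::theme_minimal()
}

#' Category counts from a triage report
#'
#' @param report A tibble from [triage()].
#' @return A ggplot object.
#' @export
plot_triage_categories <- function(report) {
  stopifnot("category" %in% names(report))
  df <- dplyr::count(report, .data$category)
  ggplot2::ggplot(df, ggplot2::aes(.data$category, .data$n)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "contigs", title = "Triage categories") +
    ggplot2::theme_minimal()
}
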