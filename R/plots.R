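# ggplot2 views of the result objects.

#' Plot per-term, per-cell cross-validated error rates
#'
#' Bars of error rate by GO term, coloured by learner, faceted on the
#' feature-selection / weighting axes of the grid.
#'
#' @param object A `method_grid_report` from [run_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot method_grid_report
#' @export
autoplot.method_grid_report <- function(object, ...) {
  df <- dplyr::filter(object, !.data$skipped) |>
    dplyr::mutate(
      preprocessing = paste0(
        ifelse(.data$weighted, "weighted", "original"), " / ",
        ifelse(.data$feature_selection, "FS", "no FS"))
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$go_term, .data$error_rate,
                                   fill = .data$learner)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~preprocessing) +
    ggplot2::labs(x = NULL, y = "10-fold CV error rate", fill = "learner") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot conditional-probability scores by feature index
#'
#' The Area 1 / Area 2 view: summed conditional probabilities per IPR
#' column, with the selected (Area 2) columns highlighted.
#'
#' @param profiles Tibble from [conditional_profiles()].
#' @param selected Optional integer vector of selected column indices, as
#'   from [select_features()].
#' @return A ggplot.
#' @export
plot_conditional_profiles <- function(profiles, selected = NULL) {
  profiles$selected <- if (is.null(selected)) {
    NA
  } else {
    profiles$column %in% as.integer(selected)
  }
  p <- ggplot2::ggplot(profiles,
                       ggplot2::aes(.data$column, .data$score))
  if (is.null(selected)) {
    p <- p + ggplot2::geom_point(alpha = 0.6)
  } else {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$selected),
                                 alpha = 0.6) +
      ggplot2::scale_colour_manual(
        values = c(`TRUE` = "#D55E00", `FALSE` = "grey60"),
        name = "Area 2")
  }
  p + ggplot2::labs(x = "IPR column index",
                    y = "sum of conditional probabilities") +
    ggplot2::theme_minimal()
}

#' Heatmap of a weighted-IPR matrix
#'
#' @param object A `weighted_ipr` from [weighted_transform()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot weighted_ipr
#' @export
autoplot.weighted_ipr <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$feature_id, .data$protein_id,
                                   fill = .data$weightsum)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "weight") +
    ggplot2::theme_minimal()
}
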