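#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a raster layer
#'
#' @param object A [grid_raster()].
#' @param ... Unused.
#' @return A ggplot raster map.
#' @export
autoplot.grid_raster <- function(object, ...) {
  df <- as_tibble.grid_raster(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)")
}

#' Plot per-replicate AUC of an ensemble
#'
#' @param object A [fit_ensemble()] object.
#' @param ... Unused.
#' @return A ggplot dot plot of train and test AUC by replicate.
#' @export
autoplot.sdm_ensemble <- function(object, ...) {
  df <- tidyr::pivot_longer(object$auc, c("auc_train", "auc_test"),
                            names_to = "split", values_to = "auc",
                            names_prefix = "auc_")
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$replicate), .data$auc,
                                   colour = .data$split)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "replicate", y = "AUC", colour = NULL)
}

#' Plot permutation variable contributions
#'
#' @param contribution Output of [variable_contribution()].
#' @param top Show at most this many predictors (default 10).
#' @return A ggplot bar chart, largest contribution on top.
#' @export
plot_contribution <- function(contribution, top = 10) {
  df <- utils::head(contribution, top)
  ggplot2::ggplot(df, ggplot2::aes(.data$contribution,
                                   stats::reorder(.data$predictor,
                                                  .data$contribution))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "contribution (%)", y = NULL)
}

#' Plot epoch-by-class proportions from buffer tallies
#'
#' @param table An [epoch_contingency()] object.
#' @return A ggplot stacked-proportion bar chart contrasting the historical
#'   and recent class composition.
#' @export
plot_epoch_classes <- function(table) {
  df <- tidy.epoch_contingency(table) |>
    dplyr::group_by(.data$epoch) |>
    dplyr::mutate(proportion = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$proportion,
                                   fill = factor(.data$class))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of buffer pixels",
                  fill = "class")
}
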