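# ggplot2 methods for the package's result types

#' @describeIn dice_per_class Bar chart of per-class Dice scores.
#' @method autoplot dice_report
#' @param object A `dice_report`.
#' @export
autoplot.dice_report <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), .data$present)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$name, .data$dice), y = .data$dice)) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::geom_hline(yintercept = attr(object, "mean"),
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Dice score",
                  title = sprintf("Mean Dice %.3f", attr(object, "mean"))) +
    ggplot2::ylim(0, 1)
}

#' @describeIn train_unet Training and validation curves over epochs.
#' @method autoplot unet_training
#' @param object A `unet_training`.
#' @export
autoplot.unet_training <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history,
                            c("train_loss", "val_loss", "val_dice"),
                            names_to = "series")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value,
                                   color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dotted") +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::guides(color = "none") +
    ggplot2::labs(x = "Epoch", y = NULL)
}

#' @method autoplot biopsy_forest_cv
#' @describeIn fit_forest Confusion-matrix tile plot of out-of-fold
#'   predictions.
#' @param object A `biopsy_forest_cv`.
#' @export
autoplot.biopsy_forest_cv <- function(object, ...) {
  sp <- object$slide_predictions
  cm <- as.data.frame(confusion_matrix(sp$label, sp$predicted))
  ggplot2::ggplot(cm, ggplot2::aes(.data$predicted, .data$reference,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#4477aa") +
    ggplot2::labs(x = "Predicted", y = "Reference", fill = "Slides") +
    ggplot2::theme_minimal()
}

#' Render a segmentation map in schema colors
#'
#' @param map A [segmentation_map()].
#' @param schema A [tissue_schema()].
#' @return A ggplot object.
#' @export
plot_segmentation_map <- function(map, schema = tissue_schema()) {
  stopifnot(inherits(map, "segmentation_map"))
  df <- tidyr::expand_grid(row = seq_len(nrow(map$labels)),
                           col = seq_len(ncol(map$labels)))
  df$class <- schema$classes$name[map$labels[cbind(df$row, df$col)] + 1L]
  pal <- setNames(schema$classes$color, schema$classes$name)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Tissue") +
    ggplot2::theme_void()
}
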