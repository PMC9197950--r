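#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

image_df <- function(x, value_name = "intensity") {
  m <- as_matrix(x)
  tibble::tibble(
    row = rep(0:(nrow(m) - 1), times = ncol(m)),
    col = rep(0:(ncol(m) - 1), each = nrow(m)),
    !!value_name := as.numeric(m)
  )
}

raster_theme <- function() {
  ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}

#' @exportS3Method ggplot2::autoplot
autoplot.gray_image <- function(object, ...) {
  ggplot2::ggplot(image_df(object), ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    raster_theme() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity")
}

#' @exportS3Method ggplot2::autoplot
autoplot.change_map <- function(object, which = c("absolute", "signed"), ...) {
  which <- match.arg(which)
  df <- image_df(object[[which]], value_name = "value")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    raster_theme() +
    ggplot2::labs(x = NULL, y = NULL, fill = which)
  if (which == "absolute") {
    p + ggplot2::scale_fill_viridis_c(limits = c(0, 1))
  } else {
    p + ggplot2::scale_fill_gradient2(low = "blue", mid = "black", high = "red")
  }
}

#' @exportS3Method ggplot2::autoplot
autoplot.change_mask <- function(object, ...) {
  df <- image_df(object$mask * 1.0, value_name = "changed")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$changed > 0.5)) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "black", `TRUE` = "white")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    raster_theme() +
    ggplot2::labs(x = NULL, y = NULL, fill = "changed")
}

#' ROC and precision-recall curves of an evaluation
#'
#' @param object An `eval_curves` object from [roc_pr_curves()].
#' @param which `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.eval_curves <- function(object, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  d <- object$curve
  if (which == "roc") {
    ggplot2::ggplot(d, ggplot2::aes(.data$fpr, .data$tpr)) +
      ggplot2::geom_path(colour = "#b2182b") +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::coord_fixed() +
      ggplot2::theme_minimal() +
      ggplot2::labs(
        x = "False positive rate", y = "True positive rate",
        title = sprintf("ROC (AUC = %.4f)", object$auc)
      )
  } else {
    ggplot2::ggplot(d, ggplot2::aes(.data$recall, .data$precision)) +
      ggplot2::geom_path(colour = "#2166ac") +
      ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
      ggplot2::theme_minimal() +
      ggplot2::labs(
        x = "Recall", y = "Precision",
        title = sprintf("PR (mAP = %.4f)", object$map)
      )
  }
}

#' Panel plot of a detection result
#'
#' Current image, rescaled absolute difference, and final change mask side
#' by side.
#'
#' @param detection A `fundus_detection` from [detect()].
#' @param pair The `image_pair` it was computed on.
#' @return A list of three ggplots (`current`, `map`, `mask`).
#' @export
plot_detection <- function(detection, pair) {
  list(
    current = autoplot(pair$current) + ggplot2::ggtitle("current image"),
    map = autoplot(detection$map) + ggplot2::ggtitle("absolute difference"),
    mask = autoplot(detection$mask) + ggplot2::ggtitle("change mask")
  )
}
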