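image_raster_df <- function(img) {
  tibble(
    x = as.vector(col(img)) - 0.5,
    y = as.vector(row(img)) - 0.5,
    intensity = as.vector(img)
  )
}

box_layer <- function(boxes, colour) {
  ggplot2::geom_rect(
    data = boxes,
    ggplot2::aes(xmin = .data$x, xmax = .data$x + .data$w,
                 ymin = .data$y, ymax = .data$y + .data$h),
    colour = colour, fill = NA, linewidth = 0.6, inherit.aes = FALSE
  )
}

us_image_plot <- function(img) {
  ggplot2::ggplot(image_raster_df(img),
                  ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::theme_void()
}

#' Plot a phantom with its truth box
#'
#' @param object An `"us_phantom"`.
#' @param ... Unused.
#' @return A ggplot: the image with the ground-truth box (green) if any.
#' @export
autoplot.us_phantom <- function(object, ...) {
  p <- us_image_plot(object$image / max(object$image))
  if (nrow(object$truth_box) > 0) {
    p <- p + box_layer(object$truth_box, "green3")
  }
  p
}

#' Plot a detection over its image
#'
#' @param object An `"us_detection"` from [detect()].
#' @param truth Optional truth box tibble drawn in green.
#' @param ... Unused.
#' @return A ggplot: image, final detection (red), optional truth (green).
#' @export
autoplot.us_detection <- function(object, truth = NULL, ...) {
  p <- us_image_plot(object$image / max(object$image))
  if (!is.null(truth) && nrow(truth) > 0) p <- p + box_layer(truth, "green3")
  if (nrow(object$final) > 0) p <- p + box_layer(object$final, "red")
  p
}

#' Plot per-image evaluation outcomes
#'
#' @param object An `"us_eval"` from [evaluate_detections()].
#' @param ... Unused.
#' @return A ggplot: IoU per image, coloured by outcome, with the 0.5
#'   true-positive bound marked.
#' @export
autoplot.us_eval <- function(object, ...) {
  df <- object$per_image
  df$iou[is.na(df$iou)] <- 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$image_id, y = .data$iou,
                                   fill = .data$outcome)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "IoU vs truth", fill = "outcome") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
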