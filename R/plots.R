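#' Plot a slice with annotations and detections overlaid
#'
#' @param image Intensity matrix.
#' @param annotation Optional [slice_annotation()] (drawn as solid
#'   segments).
#' @param detections Optional [decode_stack()] result (dashed segments).
#' @return A ggplot object.
#' @export
plot_slice <- function(image, annotation = NULL, detections = NULL) {
  H <- nrow(image); W <- ncol(image)
  df <- tibble::tibble(x = rep(0:(W - 1), each = H),
                       y = rep(0:(H - 1), times = W),
                       value = as.vector(image))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::theme_void()
  seg <- function(pairs, linetype) {
    rows <- purrr::map_dfr(pairs, function(d) {
      tibble::tibble(class = d$class, x1 = d$p1[1], y1 = d$p1[2],
                     x2 = d$p2[1], y2 = d$p2[2])
    })
    if (!nrow(rows)) return(NULL)
    ggplot2::geom_segment(
      data = rows,
      ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2,
                   yend = .data$y2, colour = .data$class),
      linewidth = 0.8, linetype = linetype, inherit.aes = FALSE)
  }
  if (!is.null(annotation)) p <- p + seg(annotation$defects, "solid")
  if (!is.null(detections)) p <- p + seg(purrr::compact(detections), "dashed")
  p + ggplot2::labs(colour = NULL)
}

#' @method autoplot fenestra_fit
#' @export
autoplot.fenestra_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object,
                                       type = c("roc", "bland_altman",
                                                "tolerance"),
                                       granularity = c("image", "tooth"),
                                       ...) {
  type <- match.arg(type)
  granularity <- match.arg(granularity)
  if (type == "roc") {
    curve <- if (granularity == "image") object$image_roc else
      object$tooth_roc
    return(
      ggplot2::ggplot(curve, ggplot2::aes(.data$fpr, .data$tpr,
                                          colour = .data$class)) +
        ggplot2::geom_line() +
        ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
        ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                      colour = NULL) +
        ggplot2::theme_minimal())
  }
  if (type == "bland_altman") {
    pairs <- dplyr::mutate(object$length_pairs,
                           mean_mm = (.data$pred_mm + .data$true_mm) / 2,
                           diff_mm = .data$pred_mm - .data$true_mm)
    return(
      ggplot2::ggplot(pairs, ggplot2::aes(.data$mean_mm, .data$diff_mm)) +
        ggplot2::geom_point(alpha = 0.5) +
        ggplot2::geom_hline(data = object$agreement,
                            ggplot2::aes(yintercept = .data$bias)) +
        ggplot2::geom_hline(data = object$agreement,
                            ggplot2::aes(yintercept = .data$loa_low),
                            linetype = "dashed") +
        ggplot2::geom_hline(data = object$agreement,
                            ggplot2::aes(yintercept = .data$loa_high),
                            linetype = "dashed") +
        ggplot2::facet_wrap(~class) +
        ggplot2::labs(x = "mean of methods (mm)",
                      y = "predicted - true (mm)") +
        ggplot2::theme_minimal())
  }
  ggplot2::ggplot(object$keypoints$tolerance_sweep,
                  ggplot2::aes(.data$tolerance_mm, .data$recognition_rate)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "match tolerance (mm)", y = "recognition rate") +
    ggplot2::theme_minimal()
}
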