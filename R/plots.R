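# ggplot2 visualisations for the pipeline's result types.

#' Overlay detected tumor cells on the slide image
#'
#' Red dots mark PD-L1-positive tumor cells, green dots PD-L1-negative tumor
#' cells; non-tumor detections are omitted.
#'
#' @param rgb H x W x 3 RGB array (0..255).
#' @param points Labelled point tibble (from [classify_nuclei()]).
#' @return A ggplot object.
#' @export
overlay_plot <- function(rgb, points) {
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  pts <- dplyr::filter(tibble::as_tibble(points), .data$is_tumor)
  pts$status <- ifelse(pts$is_positive, "positive", "negative")
  ggplot2::ggplot() +
    ggplot2::annotation_raster(aperm(rgb, c(1, 2, 3)) / 255,
                               xmin = 0, xmax = w, ymin = -h, ymax = 0) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$x, y = -.data$y,
                                     colour = .data$status),
                        size = 0.6) +
    ggplot2::scale_colour_manual(values = c(positive = "red", negative = "green3")) +
    ggplot2::coord_fixed(xlim = c(0, w), ylim = c(-h, 0), expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, colour = "tumor cell") +
    ggplot2::theme_void()
}

#' @export
autoplot.tps_result <- function(object, ...) {
  tiles <- object$tiles
  tiles$tile <- factor(seq_len(nrow(tiles)))
  long <- tidyr::pivot_longer(tiles, c("n_pt", "n_tt"),
                              names_to = "count", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tile, y = .data$n,
                                     fill = .data$count)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(title = sprintf("TPS %.1f%% (%s)", object$tps_percent,
                                  object$expression_level),
                  x = "tile", y = "cells") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.detection_pr <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = sprintf("%s = %.3f", object$auc_label, object$auc),
                  x = "recall", y = "precision") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.agreement_report <- function(object, ...) {
  ggplot2::ggplot(object$cases,
                  ggplot2::aes(x = .data$true_tps, y = .data$pred_tps,
                               colour = .data$true_level)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::coord_fixed(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::labs(title = sprintf("MAE %.2f, PCC %.3f, ACC %.1f%%",
                                  object$mae, object$pcc, 100 * object$acc3),
                  x = "reference TPS (%)", y = "predicted TPS (%)",
                  colour = "true level") +
    ggplot2::theme_minimal()
}

#' Tidy export of the confusion matrix for plotting
#'
#' @param report An `agreement_report`.
#' @return Tibble with `truth`, `predicted`, `n`.
#' @export
confusion_tidy <- function(report) {
  stopifnot(inherits(report, "agreement_report"))
  as.data.frame(as.table(report$confusion), stringsAsFactors = FALSE) |>
    tibble::as_tibble() |>
    dplyr::rename(truth = 1, predicted = 2, n = 3)
}
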