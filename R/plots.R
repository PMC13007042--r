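# ggplot2 lives in Suggests: every plot function checks for it at call time.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package")
}

#' Plot one cross section of a volume
#'
#' @param vol An [intensity_volume()], [label_volume()] or bare array.
#' @param z Slice index.
#' @return A ggplot object (raster of the slice; labels use a discrete
#'   background/fascicle/epineurium palette).
#' @export
plot_slice <- function(vol, z = 1L) {
  need_ggplot()
  is_lab <- inherits(vol, "label_volume")
  arr <- if (is_lab) vol$labels else as_intensity_array(vol)
  sl <- arr[z, , ]
  df <- data.frame(y = rep(seq_len(nrow(sl)), times = ncol(sl)),
                   x = rep(seq_len(ncol(sl)), each = nrow(sl)),
                   v = as.vector(sl))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::coord_fixed() + ggplot2::scale_y_reverse() +
    ggplot2::labs(title = sprintf("slice z = %d", z), x = "x", y = "y") +
    ggplot2::theme_minimal()
  if (is_lab) {
    df$v <- factor(df$v, levels = 0:2, labels = c("background", "fascicle", "epineurium"))
    p + ggplot2::geom_raster(data = df, ggplot2::aes(fill = .data$v)) +
      ggplot2::scale_fill_manual(values = c(background = "grey15",
                                            fascicle = "#E8B54A",
                                            epineurium = "#7A9E9F"),
                                 name = NULL)
  } else {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$v)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white", name = "intensity")
  }
}

#' Plot the instance-detection F1 curve
#'
#' @param x A `nervect_eval` or the tibble returned by [f1_curve()].
#' @return A ggplot object.
#' @export
plot_f1_curve <- function(x) {
  need_ggplot()
  df <- if (inherits(x, "nervect_eval")) x$f1_curve else x
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$mean_f1)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "IoU threshold", y = "mean instance F1") +
    ggplot2::theme_minimal()
}

#' Plot per-epoch training curves
#'
#' @param x A `nervect_model`.
#' @return A ggplot object with loss components and validation Dice.
#' @export
plot_training_log <- function(x) {
  need_ggplot()
  log <- x$log
  df <- rbind(
    data.frame(epoch = log$epoch, value = log$l_ce, series = "L_CE"),
    data.frame(epoch = log$epoch, value = log$l_dice, series = "L_Dice"),
    data.frame(epoch = log$epoch, value = log$val_dice, series = "val Dice"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_f1_curve
#' @param object A `nervect_eval`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.nervect_eval <- function(object, ...) plot_f1_curve(object)

#' @rdname plot_training_log
#' @param object A `nervect_model`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.nervect_model <- function(object, ...) plot_training_log(object)
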