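# ggplot2 visualizations. Images are drawn with geom_raster on their
# pixel grid (row 1 at the top, matching the raster convention used
# throughout the package).

image_to_df <- function(img) {
  d <- dim(img)
  tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    fill = grDevices::rgb(clamp(img[, , 1], 0, 1),
                          clamp(img[, , 2], 0, 1),
                          clamp(img[, , 3], 0, 1))
  )
}

#' Plot a tongue image with its diagnostic region map
#'
#' @param image An `H` x `W` x 3 image array.
#' @param show_bounds Draw the region boundary lines and labels.
#' @return A ggplot.
#' @export
plot_tongue <- function(image, show_bounds = TRUE) {
  image <- check_image(image)
  df <- image_to_df(image)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (show_bounds) {
    b <- region_bounds(dim(image)[1], dim(image)[2])
    p <- p +
      ggplot2::geom_hline(yintercept = c(b$r_mid, b$r_tip) + 0.5,
                          color = "white", linewidth = 0.3) +
      ggplot2::geom_vline(xintercept = c(b$c_left, b$c_right) + 0.5,
                          color = "white", linewidth = 0.3) +
      ggplot2::annotate(
        "text",
        x = c(b$w / 2, b$c_left / 2, b$w / 2, b$w / 2),
        y = c((b$r_tip + b$h) / 2, b$r_tip / 2, (b$r_mid + b$r_tip) / 2,
              b$r_mid / 2),
        label = c("A", "B", "C", "D"), color = "white", size = 3)
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.labeled_sample <- function(object, ...) {
  plot_tongue(object$image) +
    ggplot2::ggtitle(paste(names(which(object$labels == 1)), collapse = ", "))
}

#' @exportS3Method ggplot2::autoplot
autoplot.cam_map <- function(object, alpha = 0.6, ...) {
  df <- image_to_df(object$image)
  df$heat <- as.vector(object$heatmap)[df$row + (df$col - 1L) * nrow(object$heatmap)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::geom_raster(ggplot2::aes(alpha = .data$heat), fill = "red") +
    ggplot2::scale_alpha(range = c(0, alpha), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::ggtitle(sprintf("Grad-CAM: %s (%s branch)",
                             object$organ, object$branch))
}

#' @exportS3Method ggplot2::autoplot
autoplot.metrics_report <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object),
                              c("accuracy", "precision", "recall", "f1"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$organ, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.organnet_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "training loss") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ablation_table <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              tidyr::ends_with("_f1") & !tidyr::starts_with("macro"),
                              names_to = "organ", values_to = "f1")
  long$organ <- sub("_f1$", "", long$organ)
  ggplot2::ggplot(dplyr::filter(long, !is.na(.data$f1)),
                  ggplot2::aes(x = .data$organ, y = .data$method,
                               fill = .data$f1)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$f1)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "F1") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
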