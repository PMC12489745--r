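#' @export
autoplot.geno_pca <- function(object, axes = c(1, 2), colour = "region", ...) {
  df <- tidy(object, n_axes = max(axes))
  ax <- paste0("PC", axes)
  col <- if (colour %in% names(df)) colour else NULL
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]]))
  if (!is.null(col)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[col]]))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::labs(
    x = sprintf("%s (%.1f%%)", ax[1], 100 * object$var_explained[axes[1]]),
    y = sprintf("%s (%.1f%%)", ax[2], 100 * object$var_explained[axes[2]])
  ) + ggplot2::theme_minimal()
}

#' @export
autoplot.cluster_scan <- function(object, ...) {
  ggplot2::ggplot(object$scan, ggplot2::aes(.data$k, .data$bic)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = 2) +
    ggplot2::labs(x = "number of clusters", y = "BIC") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.admix_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$id, .data$proportion,
                                   fill = .data$ancestry)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "ancestry proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @export
autoplot.outlier_scan <- function(object, ...) {
  df <- object$table
  df$idx <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(.data$idx, -log10(.data$q),
                                   colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "site index", y = expression(-log[10](q))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.kinship_mat <- function(object, scale_to_min = FALSE, ...) {
  df <- tidy(object)
  if (scale_to_min) {
    m <- min(df$kinship, na.rm = TRUE)
    df$kinship <- (df$kinship - m) / (1 - m)
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$id1, .data$id2,
                                   fill = .data$kinship)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' LD decay profile plot
#'
#' @param decay output of [ld_decay()].
#' @return a ggplot.
#' @export
plot_ld_decay <- function(decay) {
  ggplot2::ggplot(decay, ggplot2::aes(.data$bin_start_kb, .data$mean_r2)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "distance (kb)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}
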