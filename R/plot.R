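#' Plot an aging-trajectory projection
#'
#' Scatter of subject-visit embeddings on the first two principal
#' components, colored by cognitive label, with arrows tracing each
#' subject's visits in order.
#'
#' @param object A [project_trajectories()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cogtraj_trajectories <- function(object, ...) {
  lab <- function(x) factor(ifelse(x == 1, "Impaired", "HC"), c("HC", "Impaired"))
  pts <- dplyr::mutate(object$points, group = lab(.data$label))
  arr <- dplyr::mutate(object$arrows, group = lab(.data$label))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                    colour = .data$group)) +
    ggplot2::geom_segment(
      data = arr,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "cm")),
      alpha = 0.6, linewidth = 0.4
    ) +
    ggplot2::geom_point(ggplot2::aes(shape = factor(.data$visit_index)), size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)",
                  100 * (if (length(object$var_explained) > 1) object$var_explained[2] else 0)),
      colour = "Status", shape = "Visit"
    ) +
    ggplot2::theme_minimal()
}

#' Plot training history
#'
#' Per-epoch loss components (classification, encoder, group alignment,
#' subject alignment), the weighted total and the validation total.
#'
#' @param object A `cogtraj_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cogtraj_fit <- function(object, ...) {
  h <- tidy(object)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$component, scales = "free_y") +
    ggplot2::labs(x = "Epoch", y = "Loss", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot per-fold cross-validation metrics
#'
#' @param object A `cogtraj_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cogtraj_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics, -"fold",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "Fold value") +
    ggplot2::theme_minimal()
}
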