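#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fuzzy c-means anchor fit
#'
#' @param x An `fcm_fit`.
#' @param ... Unused.
#' @return One row per anchor shape with its fuzzy cardinality (column sum of
#'   memberships).
#' @export
tidy.fcm_fit <- function(x, ...) {
  dplyr::mutate(x$anchors$shapes,
                cluster = dplyr::row_number(),
                fuzzy_size = colSums(x$memberships))
}

#' @rdname tidy.fcm_fit
#' @export
glance.fcm_fit <- function(x, ...) {
  tibble::tibble(c = nrow(x$anchors$shapes), m = x$anchors$config$m,
                 iterations = x$iterations, converged = x$converged,
                 objective = utils::tail(x$objective, 1))
}

#' Tidy a k-means anchor fit
#'
#' @param x A `kmeans_fit`.
#' @param ... Unused.
#' @return One row per anchor shape with its crisp cluster size.
#' @export
tidy.kmeans_fit <- function(x, ...) {
  sizes <- tabulate(x$cluster, nbins = nrow(x$anchors$shapes))
  dplyr::mutate(x$anchors$shapes, cluster = dplyr::row_number(), size = sizes)
}

#' @rdname tidy.kmeans_fit
#' @export
glance.kmeans_fit <- function(x, ...) {
  tibble::tibble(k = nrow(x$anchors$shapes), inertia = x$inertia)
}

#' Tidy a demo training run
#'
#' @param x A `demo_fit`.
#' @param ... Unused.
#' @return The per-epoch loss trace in long format.
#' @export
tidy.demo_fit <- function(x, ...) {
  tidyr::pivot_longer(x$trace, -"epoch", names_to = "split",
                      values_to = "loss")
}

#' @rdname tidy.demo_fit
#' @export
glance.demo_fit <- function(x, ...) {
  tibble::tibble(epochs = max(x$trace$epoch),
                 initial_train_loss = x$trace$train_loss[1],
                 final_train_loss = utils::tail(x$trace$train_loss, 1),
                 final_val_loss = utils::tail(x$trace$val_loss, 1),
                 train_accuracy = x$train_accuracy)
}

#' Tidy a pipeline run
#'
#' @param x A `nodule_pipeline`.
#' @param ... Unused.
#' @return The per-fold metrics tibble of the primary branch.
#' @export
tidy.nodule_pipeline <- function(x, ...) x$metrics

#' @rdname tidy.nodule_pipeline
#' @export
glance.nodule_pipeline <- function(x, ...) {
  pooled <- x$metrics[x$metrics$fold == "pooled", -1]
  dplyr::bind_cols(tibble::tibble(n_slices = x$n_slices,
                                  n_proposals = nrow(x$proposals)), pooled)
}

#' Plot an anchor fit over its box population
#'
#' @param object An `fcm_fit` or `kmeans_fit`.
#' @param ... Unused.
#' @return A ggplot: the (width, height) point cloud, coloured by (crisp or
#'   max-membership) cluster, with anchor centres overlaid.
#' @export
autoplot.fcm_fit <- function(object, ...) {
  pts <- object$points
  pts$cluster <- factor(apply(object$memberships, 1, which.max))
  anchor_plot(pts, object$anchors$shapes, "fuzzy c-means anchors")
}

#' @rdname autoplot.fcm_fit
#' @export
autoplot.kmeans_fit <- function(object, ...) {
  pts <- object$points
  pts$cluster <- factor(object$cluster)
  anchor_plot(pts, object$anchors$shapes, "k-means anchors")
}

anchor_plot <- function(pts, shapes, title) {
  ggplot2::ggplot(pts, ggplot2::aes(.data$width, .data$height)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$cluster), alpha = 0.6) +
    ggplot2::geom_point(data = shapes, shape = 4, size = 4, stroke = 1.5) +
    ggplot2::labs(title = title, x = "width (px)", y = "height (px)") +
    ggplot2::theme_minimal()
}

#' Plot a demo training loss trace
#'
#' @param object A `demo_fit`.
#' @param ... Unused.
#' @return A ggplot of training and validation loss per epoch.
#' @export
autoplot.demo_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$epoch, .data$loss, colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "demo classifier training", y = "cross-entropy") +
    ggplot2::theme_minimal()
}

#' Plot per-fold pipeline metrics
#'
#' @param object A `nodule_pipeline`.
#' @param ... Unused.
#' @return A ggplot of the five indicators per fold.
#' @export
autoplot.nodule_pipeline <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics, -"fold",
                              names_to = "indicator", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$indicator, .data$value,
                                     fill = .data$fold == "pooled")) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::guides(fill = "none") +
    ggplot2::facet_wrap(~fold) +
    ggplot2::labs(title = "detection indicators by fold", x = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a slice with boxes overlaid
#'
#' @param img An [hu_image()] or [uint8_image()].
#' @param box_df Optional box tibble to draw.
#' @return A ggplot raster with box outlines.
#' @export
plot_slice <- function(img, box_df = NULL) {
  m <- img$values
  df <- tidyr::expand_grid(y = seq_len(nrow(m)) - 0.5,
                           x = seq_len(ncol(m)) - 0.5)
  df$value <- as.vector(t(m))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(box_df) && nrow(box_df) > 0) {
    p <- p + ggplot2::geom_rect(
      data = box_df,
      ggplot2::aes(xmin = .data$x_min, xmax = .data$x_max,
                   ymin = .data$y_min, ymax = .data$y_max),
      inherit.aes = FALSE, colour = "red", fill = NA, linewidth = 0.4)
  }
  p
}
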