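# ggplot2 visualisations for the fitted-object classes.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a mixture fit over the clustered data
#'
#' Scatter of the two clustering features colored by max-posterior
#' assignment, with the component means marked.
#'
#' @param object A `gmm_fit` in two dimensions.
#' @param data The data the model was fitted to.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gmm_fit <- function(object, data, ...) {
  stopifnot(object$k == 2L)
  X <- as_feature_matrix(data, object$vars)
  df <- tibble::as_tibble(as.data.frame(X))
  df$cluster <- factor(assign_clusters(object, data))
  centers <- tibble::as_tibble(as.data.frame(object$means))
  names(centers) <- object$vars
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[object$vars[1L]]], y = .data[[object$vars[2L]]],
    colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_point(data = centers, inherit.aes = FALSE,
                        ggplot2::aes(x = .data[[object$vars[1L]]],
                                     y = .data[[object$vars[2L]]]),
                        shape = 4, size = 4, stroke = 1.5) +
    ggplot2::labs(colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot a BIC selection trace
#'
#' BIC against the number of components; the minimum marks the selected
#' model.
#'
#' @param object A `gmm_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gmm_selection <- function(object, ...) {
  ggplot2::ggplot(object$selection, ggplot2::aes(x = .data$K, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = object$selection[
      object$selection$K == object$selected_k, ],
      colour = "red", size = 3) +
    ggplot2::labs(x = "number of components", y = "BIC") +
    ggplot2::theme_minimal()
}

#' Plot PCA scores
#'
#' First two principal-component scores of projected data.
#'
#' @param object An `rtdc_pca`.
#' @param data Data to project (defaults cannot be stored; pass the event
#'   table).
#' @param colour Optional column of `data` used to colour points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rtdc_pca <- function(object, data, colour = NULL, ...) {
  sc <- pca_project(object, data)
  if (!is.null(colour)) sc[[colour]] <- data[[colour]]
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point(alpha = 0.4, size = 0.8)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                            alpha = 0.6, size = 0.8)
  }
}

#' Plot a bootstrap differential-deformation distribution
#'
#' Histogram of the bootstrap differences with the mean marked.
#'
#' @param object A `bootstrap_dd`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bootstrap_dd <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dd)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = mean(df$dd), colour = "red") +
    ggplot2::labs(x = "differential deformation", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot an overlap-assay result
#'
#' Selected component count and assignment accuracy against the
#' density-contour overlap.
#'
#' @param data An [overlap_assay()] tibble.
#' @return A ggplot object.
#' @export
plot_overlap_assay <- function(data) {
  long <- tidyr::pivot_longer(data, c("selected_k", "accuracy"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$overlap_pct, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "contour overlap (%)", y = NULL) +
    ggplot2::theme_minimal()
}
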