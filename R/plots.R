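#' @export
autoplot.image8 <- function(object, ...) {
  m <- as.matrix(object)
  d <- tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    intensity = as.vector(m)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = img_id(object), x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot the score distributions behind an audit
#'
#' Histograms of detective scores by dataset label — the visual counterpart
#' of the AUC readout: overlapping distributions mean no detectable
#' shortcut.
#'
#' @param ensemble A `detective_ensemble`.
#' @param dataset A [labeled_dataset()].
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_score_distributions <- function(ensemble, dataset, bins = 30) {
  d <- tibble::tibble(score = predict_scores(ensemble, dataset),
                      label = factor(dataset$label))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, fill = .data$label)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6,
                            position = "identity") +
    ggplot2::labs(x = "detective score", y = "count",
                  title = dataset_name(dataset)) +
    ggplot2::theme_minimal()
}
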