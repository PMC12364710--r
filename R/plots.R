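#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_col geom_density
#'   geom_point geom_errorbar scale_fill_gradient2 labs theme_minimal
#'   facet_wrap position_dodge geom_hline
#' @export
ggplot2::autoplot

#' Heatmap of a representational dissimilarity matrix
#'
#' @param object An `rdm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rdm <- function(object, ...) {
  df <- as_tibble(object)
  full <- dplyr::bind_rows(
    df,
    dplyr::rename(df, stimulus_a = "stimulus_b", stimulus_b = "stimulus_a"),
    tibble(stimulus_a = object$stimulus_ids,
           stimulus_b = object$stimulus_ids, distance = 0))
  ggplot(full, aes(.data$stimulus_a, .data$stimulus_b,
                   fill = .data$distance)) +
    geom_tile() +
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                         midpoint = 1, limits = c(0, 2)) +
    labs(x = NULL, y = NULL, fill = "1 - r") +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Bar chart of noise-ceiling-corrected model comparison scores
#'
#' Mean corrected correlation per model and ROI, with per-participant points.
#'
#' @param object A `model_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.model_comparison <- function(object, ...) {
  summ <- glance(object)
  ggplot(summ, aes(.data$model, .data$mean_corrected_r, fill = .data$model)) +
    geom_col() +
    geom_point(data = object$scores,
               aes(.data$model, .data$corrected_r), inherit.aes = FALSE,
               alpha = 0.5, size = 0.8) +
    facet_wrap(~roi) +
    labs(x = NULL, y = "noise-ceiling-corrected r") +
    theme_minimal() +
    ggplot2::theme(legend.position = "none",
                   axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Density of decoding prediction scores
#'
#' Kernel density of the per-stimulus Pearson correlations between predicted
#' and target embeddings; the dashed line marks the mean inter-caption
#' consistency ceiling if supplied.
#'
#' @param object A `lookup_result`.
#' @param ceiling Optional scalar noise ceiling to annotate.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lookup_result <- function(object, ceiling = NULL, ...) {
  p <- ggplot(object, aes(.data$prediction_score)) +
    geom_density(fill = "steelblue", alpha = 0.4) +
    labs(x = "prediction score (Pearson r)", y = "density") +
    theme_minimal()
  if (!is.null(ceiling)) {
    p <- p + geom_hline(yintercept = 0) +
      ggplot2::geom_vline(xintercept = ceiling, linetype = "dashed")
  }
  p
}

#' Axial slice of a searchlight map
#'
#' @param map A [searchlight_rsa()] tibble.
#' @param slice_z Which z slice to show (default: the modal z).
#' @return A ggplot.
#' @export
plot_searchlight_slice <- function(map, slice_z = NULL) {
  if (is.null(slice_z)) {
    slice_z <- as.integer(names(sort(table(map$z), decreasing = TRUE))[1])
  }
  df <- dplyr::filter(map, .data$z == slice_z)
  ggplot(df, aes(.data$x, .data$y, fill = .data$mean_r)) +
    geom_tile() +
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                         midpoint = 0) +
    labs(title = sprintf("searchlight RSA, z = %d", slice_z),
         fill = "mean r") +
    theme_minimal()
}
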