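#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an encoding or decoding model
#'
#' One row per target (voxel for encoding, embedding dimension for decoding)
#' with the selected regularization fraction, the mean cross-validated
#' correlation at that fraction, the weight norm and the flagged status.
#'
#' @param x An `encoding_model` (or `decoding_model`).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.encoding_model <- function(x, ...) {
  best_idx <- match(x$best_fraction, x$fractions)
  tibble(
    target = seq_along(x$best_fraction),
    best_fraction = x$best_fraction,
    cv_r = x$cv_r[cbind(seq_along(best_idx), best_idx)],
    weight_norm = sqrt(colSums(x$coef^2)),
    flagged = x$flagged
  )
}

#' @rdname tidy.encoding_model
#' @export
glance.encoding_model <- function(x, ...) {
  tibble(n = x$n, n_predictors = x$q, n_targets = length(x$intercept),
         n_fractions = length(x$fractions),
         mean_best_fraction = mean(x$best_fraction[!x$flagged]),
         n_flagged = sum(x$flagged))
}

#' Tidy a sampled-RSA result
#'
#' @param x A `sampled_rsa`.
#' @param ... Unused.
#' @return A tibble with one row per subset split.
#' @export
tidy.sampled_rsa <- function(x, ...) {
  tibble(split = seq_len(x$n_splits), r = x$split_r)
}

#' @rdname tidy.sampled_rsa
#' @export
glance.sampled_rsa <- function(x, ...) {
  tibble(mean_r = x$mean_r, n_splits = x$n_splits)
}

#' Tidy a model comparison
#'
#' @param x A `model_comparison`.
#' @param ... Unused.
#' @return The per-model/participant/ROI score tibble.
#' @export
tidy.model_comparison <- function(x, ...) x$scores

#' @rdname tidy.model_comparison
#' @export
glance.model_comparison <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$scores, .data$roi, .data$model),
    mean_corrected_r = mean(.data$corrected_r, na.rm = TRUE),
    .groups = "drop")
}

#' Tidy a readout probe result
#'
#' @param x A `readout_result`.
#' @param ... Unused.
#' @return A one-row tibble with the test cosine, floor and fit diagnostics.
#' @export
tidy.readout_result <- function(x, ...) {
  tibble(test_cosine = x$test_cosine, floor = x$floor, n_train = x$n_train,
         n_test = x$n_test, n_iter = length(x$loss_trace) - 1L,
         converged = x$converged)
}

#' Tidy a sentence contrast
#'
#' @param x A `sentence_contrast`.
#' @param ... Unused.
#' @return The per-voxel group tibble (`voxel`, `estimate`, `t`, `p`).
#' @export
tidy.sentence_contrast <- function(x, ...) x$group
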