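#' Fit a brain-to-embedding decoding model
#'
#' The mirror image of the encoding model: voxel responses (restricted to an
#' ROI mask) are the predictors and the mean caption embeddings are the
#' targets. The same fractional-ridge cross-validation machinery selects the
#' regularization fraction per embedding dimension.
#'
#' @param Y Voxel responses (`avg_responses` or matrix, `n x p`).
#' @param X Mean caption embeddings (`n x d`), the decoding targets.
#' @param roi Optional voxel subset (indices or logical) restricting the
#'   predictors; defaults to all voxels.
#' @param fractions,k_folds,seed As in [fit_encoding_model()].
#' @return A `decoding_model` (inherits `encoding_model`) with an extra `roi`
#'   field.
#' @export
fit_decoding_model <- function(Y, X, roi = NULL, fractions = fraction_grid(),
                               k_folds = 5L, seed = 1L) {
  if (inherits(Y, "avg_responses")) Y <- Y$values
  Y <- as.matrix(Y)
  if (is.null(roi)) roi <- seq_len(ncol(Y))
  if (is.logical(roi)) roi <- which(roi)
  fit <- fit_encoding_model(Y[, roi, drop = FALSE], X, fractions = fractions,
                            k_folds = k_folds, seed = seed)
  fit$roi <- roi
  class(fit) <- c("decoding_model", class(fit))
  fit
}

#' Predict embeddings from voxel responses
#'
#' @param object A `decoding_model`.
#' @param newdata Voxel responses (`avg_responses` or matrix over the full
#'   voxel space; the model's ROI restriction is applied).
#' @param ... Unused.
#' @return Matrix of predicted embeddings.
#' @export
predict.decoding_model <- function(object, newdata, ...) {
  if (inherits(newdata, "avg_responses")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$q) {
    newdata <- newdata[, object$roi, drop = FALSE]
  }
  NextMethod(object, newdata = newdata)
}

#' Pearson prediction score between predicted and target embeddings
#'
#' One correlation per test stimulus, computed across embedding dimensions.
#' A constant vector has an undefined correlation and yields `NA`.
#'
#' @param pred Predicted embeddings (matrix, rows = stimuli) or one vector.
#' @param target Target embeddings of the same shape.
#' @return Numeric vector of per-stimulus correlations.
#' @export
prediction_score <- function(pred, target) {
  if (is.null(dim(pred))) pred <- matrix(pred, 1)
  if (is.null(dim(target))) target <- matrix(target, 1)
  if (!identical(dim(pred), dim(target))) {
    abort("`pred` and `target` must have the same shape.")
  }
  paired_col_cor(t(pred), t(target))
}

#' Inter-caption consistency noise ceiling
#'
#' For each stimulus, the ceiling on embedding-prediction accuracy given
#' inter-rater caption variability: the Pearson correlation between each
#' caption's embedding and the average of the remaining captions' embeddings,
#' averaged over captions.
#'
#' @param caption_embeddings Array `n_stimuli x n_captions x d`, or a
#'   `scene_set`.
#' @return A tibble with `stimulus` (index) and `ceiling`.
#' @export
caption_noise_ceiling <- function(caption_embeddings) {
  if (inherits(caption_embeddings, "scene_set")) {
    caption_embeddings <- caption_embeddings$caption_embeddings
  }
  stopifnot(length(dim(caption_embeddings)) == 3L)
  n_cap <- dim(caption_embeddings)[2]
  if (n_cap < 3L) abort("At least 3 captions per stimulus are required.")
  n <- dim(caption_embeddings)[1]
  ceilings <- vapply(seq_len(n), function(i) {
    caps <- caption_embeddings[i, , ]  # n_captions x d
    tot <- colSums(caps)
    rs <- vapply(seq_len(n_cap), function(j) {
      others <- (tot - caps[j, ]) / (n_cap - 1)
      suppressWarnings(cor(caps[j, ], others))
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  tibble(stimulus = seq_len(n), ceiling = ceilings)
}
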