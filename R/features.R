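#' Feature matrix container
#'
#' @param values Matrix `n_stimuli x q`.
#' @param model_name Label for the feature model.
#' @param stimulus_ids Row ids.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, model_name, stimulus_ids) {
  values <- as.matrix(values)
  stopifnot(length(stimulus_ids) == nrow(values))
  if (anyNA(values) || any(!is.finite(values))) {
    abort("Feature values must be finite.")
  }
  structure(list(values = values, model_name = model_name,
                 stimulus_ids = as.character(stimulus_ids)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> '%s': %d stimuli x %d features\n",
              x$model_name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Mean caption-embedding features
#'
#' The canonical sentence-embedding feature model: the arithmetic mean of the
#' per-caption embeddings of each stimulus, averaging out inter-rater
#' differences.
#'
#' @param x A `scene_set`, or an array `n_stimuli x n_captions x d`.
#' @param stimulus_ids Ids when `x` is an array.
#' @return A `feature_matrix` named `"caption_mean"`.
#' @export
mean_caption_embedding <- function(x, stimulus_ids = NULL) {
  if (inherits(x, "scene_set")) {
    arr <- x$caption_embeddings
    stimulus_ids <- x$scene_ids
  } else {
    arr <- x
    if (length(dim(arr)) != 3L) abort("Expected a 3D caption array.")
    if (is.null(stimulus_ids)) stimulus_ids <- as.character(seq_len(dim(arr)[1]))
  }
  feature_matrix(apply(arr, c(1, 3), mean), "caption_mean", stimulus_ids)
}

#' Multi-hot category features
#'
#' Binary vectors with a 1 for each category present in a stimulus.
#'
#' @param labels Either a binary matrix (`n x m`), or a list of integer
#'   category-id vectors, or a `scene_set` (its `categories` are used).
#' @param n_categories Size of the label universe when `labels` is a list.
#' @param stimulus_ids Row ids (taken from the scene set when given one).
#' @return A `feature_matrix` named `"multi_hot"`. Scenes with no category
#'   produce an all-zero row; downstream RDM code treats their pattern as
#'   degenerate (neutral distance 1, with a warning).
#' @export
multi_hot_features <- function(labels, n_categories = NULL,
                               stimulus_ids = NULL) {
  if (inherits(labels, "scene_set")) {
    stimulus_ids <- labels$scene_ids
    mat <- labels$categories
  } else if (is.list(labels)) {
    if (is.null(n_categories)) {
      abort("`n_categories` is required when labels are given as id lists.")
    }
    mat <- matrix(0L, length(labels), n_categories)
    for (i in seq_along(labels)) {
      ids <- labels[[i]]
      if (length(ids)) {
        if (any(ids < 1 | ids > n_categories)) {
          abort("Unknown category id in labels.")
        }
        mat[i, ids] <- 1L
      }
    }
  } else {
    mat <- as.matrix(labels)
    if (!all(mat %in% c(0, 1))) abort("Multi-hot matrix must be binary.")
  }
  if (is.null(stimulus_ids)) stimulus_ids <- as.character(seq_len(nrow(mat)))
  feature_matrix(mat, "multi_hot", stimulus_ids)
}

#' Averaged word-vector features
#'
#' The mean word vector over all words of all captions of a stimulus — the
#' order-free, additive word-embedding control model. A stimulus with no
#' words receives the supplied neutral vector (the synthetic analogue of
#' embedding a semantically empty placeholder word).
#'
#' @param x A `scene_set`, or a list (per stimulus) of lists (per caption)
#'   with elements `vectors` (matrix words x d_w) and `tags`.
#' @param neutral_vector Fallback vector for empty word sets.
#' @param stimulus_ids Row ids when `x` is a plain list.
#' @param keep Optional tag set; only words whose tag is in `keep` are
#'   averaged (used by [pos_filtered_features()]).
#' @param model_name Feature-model label.
#' @return A `feature_matrix`.
#' @export
averaged_word_features <- function(x, neutral_vector, stimulus_ids = NULL,
                                   keep = NULL, model_name = "word_mean") {
  if (inherits(x, "scene_set")) {
    stimulus_ids <- x$scene_ids
    x <- x$word_vectors
  }
  if (is.null(stimulus_ids)) stimulus_ids <- as.character(seq_along(x))
  d_w <- length(neutral_vector)
  vals <- t(vapply(x, function(scene) {
    mats <- lapply(scene, function(cap) {
      v <- cap$vectors
      if (ncol(v) != d_w) abort("Word-vector dimension mismatch.")
      if (!is.null(keep)) v <- v[cap$tags %in% keep, , drop = FALSE]
      v
    })
    allw <- do.call(rbind, mats)
    if (!nrow(allw)) as.numeric(neutral_vector) else colMeans(allw)
  }, numeric(d_w)))
  feature_matrix(vals, model_name, stimulus_ids)
}

#' Part-of-speech-filtered word features
#'
#' Restricts the averaged word-vector model to words carrying a given tag
#' (e.g. nouns only, or verbs only) before averaging. Stimuli with no word
#' surviving the filter fall back to the neutral vector.
#'
#' @inheritParams averaged_word_features
#' @param keep Character vector of tags to keep (e.g. `"noun"`).
#' @return A `feature_matrix` named `"word_<tags>"`.
#' @export
pos_filtered_features <- function(x, keep, neutral_vector,
                                  stimulus_ids = NULL) {
  averaged_word_features(
    x, neutral_vector, stimulus_ids = stimulus_ids, keep = keep,
    model_name = paste0("word_", paste(keep, collapse = "+")))
}
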