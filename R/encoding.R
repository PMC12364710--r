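#' Fit a voxelwise (or featurewise) fractional ridge model
#'
#' Fits the linear map from design `X` to every target column of `Y` with
#' fractional ridge regression, selecting the regularization fraction per
#' target by k-fold cross-validation: the fraction maximizing the mean
#' cross-validated Pearson correlation between predicted and held-out values
#' is retained (ties go to the smallest fraction, i.e. the most regularized
#' solution) and the final weights are refit on all training data at that
#' fraction. Used with embeddings as `X` and voxel responses as `Y` this is
#' the encoding model; [fit_decoding_model()] swaps the roles.
#'
#' `X` and `Y` are centred on training statistics; the intercept is restored
#' at prediction. A target that is constant in training has no defined
#' correlation: it gets the smallest fraction, zero weights, and is flagged.
#'
#' @param X Design matrix `n x q` (e.g. mean caption embeddings).
#' @param Y Target matrix `n x T` (e.g. average voxel responses, or an
#'   `avg_responses`).
#' @param fractions Regularization-fraction grid (default [fraction_grid()],
#'   20 fractions).
#' @param k_folds Number of CV folds (default 5; must be < n).
#' @param seed Seed for the fold shuffle.
#' @return An `encoding_model`: list with `coef` (`q x T`), `intercept`
#'   (length T), `x_center`, `best_fraction` (per target), `cv_r`
#'   (`T x length(fractions)` mean CV correlation), `fractions`, `flagged`
#'   (logical per target), `n`, `q`.
#' @export
fit_encoding_model <- function(X, Y, fractions = fraction_grid(),
                               k_folds = 5L, seed = 1L) {
  if (inherits(Y, "avg_responses")) Y <- Y$values
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) abort("`X` and `Y` must have the same rows.")
  k_folds <- check_count(k_folds, "k_folds", min = 2L)
  if (n <= k_folds) abort("Need more training rows than folds.")
  fractions <- sort(unique(fractions))
  n_f <- length(fractions)
  n_t <- ncol(Y)

  flagged <- apply(Y, 2, sd) == 0

  # contiguous fold blocks over a seeded shuffle of the training order
  fold_id <- integer(n)
  with_seed(derive_seed(seed, "cv_folds"), {
    ord <- sample.int(n)
    blocks <- rep(seq_len(k_folds),
                  diff(floor(seq(0, n, length.out = k_folds + 1))))
    fold_id[ord] <- blocks
  })

  cv_sum <- matrix(0, n_t, n_f)
  cv_cnt <- matrix(0, n_t, n_f)
  for (fold in seq_len(k_folds)) {
    tr <- fold_id != fold
    Xtr <- X[tr, , drop = FALSE]
    Ytr <- Y[tr, , drop = FALSE]
    xc <- colMeans(Xtr)
    yc <- colMeans(Ytr)
    path <- fractional_ridge_path(sweep(Xtr, 2, xc), sweep(Ytr, 2, yc),
                                  fractions)
    Xva <- sweep(X[!tr, , drop = FALSE], 2, xc)
    Yva <- Y[!tr, , drop = FALSE]
    for (f_i in seq_len(n_f)) {
      pred <- Xva %*% path$coefficients[, , f_i] +
        matrix(yc, nrow(Xva), n_t, byrow = TRUE)
      r <- paired_col_cor(pred, Yva)
      ok <- !is.na(r)
      cv_sum[ok, f_i] <- cv_sum[ok, f_i] + r[ok]
      cv_cnt[ok, f_i] <- cv_cnt[ok, f_i] + 1
    }
  }
  cv_r <- cv_sum / cv_cnt
  cv_r[cv_cnt == 0] <- NA_real_

  best_idx <- apply(cv_r, 1, function(row) {
    if (all(is.na(row))) return(1L)
    which.max(row)  # fractions ascending: first max = smallest fraction
  })
  best_idx[flagged] <- 1L
  best_fraction <- fractions[best_idx]

  # refit on all data at the selected fraction, grouped by fraction
  xc <- colMeans(X)
  yc <- colMeans(Y)
  Xc <- sweep(X, 2, xc)
  Yc <- sweep(Y, 2, yc)
  coef <- matrix(0, ncol(X), n_t)
  for (f_i in sort(unique(best_idx))) {
    cols <- which(best_idx == f_i & !flagged)
    if (!length(cols)) next
    path <- fractional_ridge_path(Xc, Yc[, cols, drop = FALSE],
                                  fractions[f_i])
    coef[, cols] <- path$coefficients[, , 1]
  }
  coef[, flagged] <- 0
  if (any(flagged)) {
    warn(sprintf("%d constant target(s) in training; weights set to 0.",
                 sum(flagged)))
  }

  structure(
    list(coef = coef, intercept = yc, x_center = xc,
         best_fraction = best_fraction, cv_r = cv_r, fractions = fractions,
         flagged = flagged, n = n, q = ncol(X)),
    class = "encoding_model"
  )
}

#' @export
print.encoding_model <- function(x, ...) {
  cat(sprintf(
    "<encoding_model> %d predictors -> %d targets, n = %d, %d-fraction grid\n",
    x$q, length(x$intercept), x$n, length(x$fractions)))
  invisible(x)
}

#' @export
predict.encoding_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$q) abort("Predictor dimension mismatch.")
  sweep(newdata, 2, object$x_center) %*% object$coef +
    matrix(object$intercept, nrow(newdata), length(object$intercept),
           byrow = TRUE)
}

#' Per-target test correlation of an encoding model
#'
#' Pearson correlation, per target (voxel), between predicted and observed
#' test values. Test stimuli must be disjoint from training. Flagged targets
#' propagate `NA`.
#'
#' @param model An `encoding_model`.
#' @param X Test design matrix.
#' @param Y Test targets (matrix or `avg_responses`).
#' @return A tibble with `target` and `r`.
#' @export
evaluate_encoding <- function(model, X, Y) {
  if (inherits(Y, "avg_responses")) Y <- Y$values
  Y <- as.matrix(Y)
  if (nrow(Y) < 3L) abort("At least 3 test stimuli are required.")
  pred <- predict(model, X)
  r <- paired_col_cor(pred, Y)
  r[model$flagged] <- NA_real_
  tibble(target = seq_along(r), r = r)
}

#' Cross-participant encoding evaluation
#'
#' Evaluates the encoding model fitted on one participant on another
#' participant's shared-stimulus responses (a generalization test of the
#' learned feature-to-voxel mapping).
#'
#' @param models List of `encoding_model`, one per participant.
#' @param responses List of test `avg_responses` over the same shared
#'   stimuli.
#' @param X Test design matrix (shared-stimulus embeddings).
#' @param train Index of the participant whose model is used.
#' @param test Index of the participant providing the test responses; must
#'   differ from `train`.
#' @return A tibble with `target` and `r` (as [evaluate_encoding()]).
#' @export
cross_participant_encode <- function(models, responses, X, train, test) {
  if (train == test) {
    abort("`train` and `test` participants must differ for cross-participant evaluation.")
  }
  evaluate_encoding(models[[train]], X, responses[[test]])
}

#' Interparticipant voxel agreement on shared stimuli
#'
#' For each voxel and participant: Pearson correlation between that
#' participant's responses over the shared stimuli and the average response
#' of the remaining participants. This upper-bounds what any
#' stimulus-driven encoding model can achieve per voxel.
#'
#' @param responses List of `avg_responses` over the same shared stimuli, one
#'   per participant, common voxel space.
#' @return A tibble with `participant`, `voxel`, `agreement`.
#' @export
interparticipant_agreement <- function(responses) {
  if (length(responses) < 2L) abort("At least 2 participants are required.")
  ids <- responses[[1]]$stimulus_ids
  for (r in responses) {
    if (!identical(r$stimulus_ids, ids)) {
      abort("All participants must share the same stimuli in the same order.")
    }
  }
  mats <- lapply(responses, `[[`, "values")
  total <- Reduce(`+`, mats)
  purrr::map_dfr(seq_along(mats), function(i) {
    others <- (total - mats[[i]]) / (length(mats) - 1)
    tibble(participant = i, voxel = seq_len(ncol(mats[[i]])),
           agreement = paired_col_cor(mats[[i]], others))
  })
}
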