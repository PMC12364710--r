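#' Sentence-contrast prediction maps from encoding models
#'
#' Given two sets of sentence embeddings (conditions A and B), each
#' participant's encoding model predicts the voxel activity evoked by every
#' sentence; the per-voxel contrast is the mean predicted activity over
#' condition A minus the mean over condition B. A group two-tailed t-test
#' across participants is computed per voxel. By design no FDR correction is
#' applied to this exploratory map (unlike the RSA group maps).
#'
#' @param models List of `encoding_model`, one per participant.
#' @param condition_a,condition_b Matrices of sentence embeddings (rows =
#'   sentences, columns = embedding dimensions, same dimension as the models'
#'   design).
#' @return A `sentence_contrast` object: list with `contrast` (participants x
#'   voxels matrix) and `group` (tibble with `voxel`, `estimate`, `t`, `p`).
#' @export
sentence_contrast <- function(models, condition_a, condition_b) {
  condition_a <- as.matrix(condition_a)
  condition_b <- as.matrix(condition_b)
  if (!nrow(condition_a) || !nrow(condition_b)) {
    abort("Both conditions need at least one sentence.")
  }
  if (ncol(condition_a) != ncol(condition_b)) {
    abort("Conditions must share the embedding dimension.")
  }
  q <- models[[1]]$q
  if (ncol(condition_a) != q) {
    abort("Sentence embedding dimension does not match the encoding models.")
  }

  contrast <- t(vapply(models, function(m) {
    colMeans(predict(m, condition_a)) - colMeans(predict(m, condition_b))
  }, numeric(length(models[[1]]$intercept))))

  n <- nrow(contrast)
  est <- colMeans(contrast)
  se <- apply(contrast, 2, sd) / sqrt(n)
  tstat <- est / se
  tstat[se == 0 & est == 0] <- 0
  pval <- 2 * pt(-abs(tstat), df = n - 1)
  pval[se == 0 & est == 0] <- 1

  structure(
    list(contrast = contrast,
         group = tibble(voxel = seq_along(est), estimate = est, t = tstat,
                        p = pval)),
    class = "sentence_contrast"
  )
}

#' @export
print.sentence_contrast <- function(x, ...) {
  cat(sprintf("<sentence_contrast> %d participants x %d voxels\n",
              nrow(x$contrast), ncol(x$contrast)))
  invisible(x)
}
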