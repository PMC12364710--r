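#' Nearest dictionary entry by Pearson correlation
#'
#' For each predicted embedding, computes the Pearson correlation with every
#' dictionary entry and returns the entry with the maximal correlation (ties
#' broken by lowest entry index, deterministically). Correlation — not cosine
#' — is used, i.e. vectors are centred before normalization. Scoring is done
#' in fixed-size blocks of dictionary entries so memory stays bounded; the
#' result is independent of the block size.
#'
#' @param pred Predicted embeddings (matrix rows = stimuli, or one vector).
#' @param dict A `caption_dictionary` (or a plain embedding matrix).
#' @param block_size Dictionary entries scored per block (default 10000).
#' @return A tibble with `stimulus`, `best_entry` (index into the
#'   dictionary), `best_entry_id`, `best_r`.
#' @export
dictionary_lookup <- function(pred, dict, block_size = 10000L) {
  if (is.null(dim(pred))) pred <- matrix(pred, 1)
  pred <- as.matrix(pred)
  if (inherits(dict, "caption_dictionary")) {
    emb <- dict$embeddings
    ids <- dict$entry_ids
  } else {
    emb <- as.matrix(dict)
    ids <- rownames(emb)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(emb)))
  }
  if (!nrow(emb)) abort("Dictionary is empty.")
  if (ncol(emb) != ncol(pred)) {
    abort("Dictionary embedding dimension does not match predictions.")
  }
  dsd <- apply(emb, 1, sd)
  if (all(dsd == 0)) abort("All dictionary entries are constant.")
  block_size <- check_count(block_size, "block_size")

  # centre and normalize predictions across dimensions
  pc <- pred - rowMeans(pred)
  pn <- sqrt(rowSums(pc^2))
  pn[pn == 0] <- NA_real_
  pc <- pc / pn

  n <- nrow(pred)
  best_r <- rep(-Inf, n)
  best_idx <- rep(NA_integer_, n)
  start <- 1L
  while (start <= nrow(emb)) {
    end <- min(start + block_size - 1L, nrow(emb))
    dblock <- emb[start:end, , drop = FALSE]
    dc <- dblock - rowMeans(dblock)
    dn <- sqrt(rowSums(dc^2))
    dn[dn == 0] <- Inf  # constant entries can never win
    dc <- dc / dn
    r <- pc %*% t(dc)  # n x block
    blk_best <- max.col(r, ties.method = "first")
    blk_r <- r[cbind(seq_len(n), blk_best)]
    improve <- !is.na(blk_r) & blk_r > best_r
    best_r[improve] <- blk_r[improve]
    best_idx[improve] <- start - 1L + blk_best[improve]
    start <- end + 1L
  }
  tibble(stimulus = seq_len(n), best_entry = best_idx,
         best_entry_id = ids[best_idx], best_r = best_r)
}

#' Rank prediction scores within a test set
#'
#' Orders stimuli by descending prediction score: rank 0 is the best
#' prediction in the set, rank `n - 1` the worst (515 test stimuli give worst
#' rank 514). Ties are broken by stimulus index.
#'
#' @param scores Numeric vector of per-stimulus prediction scores.
#' @return Integer vector of ranks, a permutation of `0:(n-1)`.
#' @export
#' @examples
#' rank_predictions(c(0.9, 0.1, 0.5))  # 0 2 1
rank_predictions <- function(scores) {
  if (!length(scores)) abort("`scores` must be non-empty.")
  ord <- order(-scores, seq_along(scores))
  out <- integer(length(scores))
  out[ord] <- seq_along(scores) - 1L
  out
}

#' Decode a test set and summarize lookup results
#'
#' Convenience pipeline: predict embeddings from test responses, score them
#' against the target embeddings, retrieve the best dictionary entry per
#' stimulus, and rank the prediction scores.
#'
#' @param model A `decoding_model`.
#' @param responses Test voxel responses (`avg_responses` or matrix).
#' @param targets Target embeddings (`n x d`).
#' @param dict A `caption_dictionary`.
#' @param stimulus_ids Optional stimulus ids for the output.
#' @return A `lookup_result` tibble: `stimulus_id`, `prediction_score`,
#'   `best_entry_id`, `lookup_r`, `retrieved_scene`, `rank`.
#' @export
decode_lookup <- function(model, responses, targets, dict,
                          stimulus_ids = NULL) {
  if (inherits(responses, "avg_responses")) {
    if (is.null(stimulus_ids)) stimulus_ids <- responses$stimulus_ids
    responses <- responses$values
  }
  pred <- predict(model, responses)
  if (is.null(stimulus_ids)) stimulus_ids <- as.character(seq_len(nrow(pred)))
  scores <- prediction_score(pred, as.matrix(targets))
  hits <- dictionary_lookup(pred, dict)
  retrieved <- if (inherits(dict, "caption_dictionary")) {
    dict$scene_id[hits$best_entry]
  } else {
    NA_character_
  }
  structure(
    tibble(stimulus_id = stimulus_ids, prediction_score = scores,
           best_entry_id = hits$best_entry_id, lookup_r = hits$best_r,
           retrieved_scene = retrieved, rank = rank_predictions(scores)),
    class = c("lookup_result", class(tibble()))
  )
}
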