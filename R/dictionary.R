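#' Build a synthetic caption dictionary for lookup decoding
#'
#' The dictionary contains one paraphrase entry per scene (the scene's true
#' embedding plus Gaussian jitter) and `n_distractors` distractor entries.
#' Distractors are drawn as fresh latent vectors pushed through the scene
#' set's latent-to-embedding map, plus isotropic spread, so they occupy the
#' same region of embedding space as real captions. Entry order is a seeded
#' permutation of targets and distractors, deterministic given the seed.
#'
#' @param scenes A `scene_set`.
#' @param n_distractors Number of distractor entries (>= 0).
#' @param distractor_spread Sd of the isotropic component added to each
#'   distractor embedding.
#' @param paraphrase_jitter Sd of the jitter on each scene's paraphrase entry
#'   (0 = exact true embeddings).
#' @param seed Integer seed.
#'
#' @return A `caption_dictionary`: list with `entry_ids`, `texts` (synthetic
#'   tokens), `embeddings` (`n_entries x d`), and `scene_id` (the matching
#'   scene for paraphrase entries, `NA` for distractors).
#' @export
build_caption_dictionary <- function(scenes, n_distractors = 0L,
                                     distractor_spread = 0.5,
                                     paraphrase_jitter = 0, seed = 1L) {
  stopifnot(inherits(scenes, "scene_set"))
  n_distractors <- check_count(n_distractors, "n_distractors", min = 0L)
  distractor_spread <- check_number(distractor_spread, "distractor_spread",
                                    min = 0)
  paraphrase_jitter <- check_number(paraphrase_jitter, "paraphrase_jitter",
                                    min = 0)
  d <- ncol(scenes$true_embedding)
  k <- ncol(scenes$latent)
  A <- attr(scenes, "latent_map")

  with_seed(derive_seed(seed, "dictionary"), {
    targets <- scenes$true_embedding
    if (paraphrase_jitter > 0) {
      targets <- targets + matrix(rnorm(length(targets),
                                        sd = paraphrase_jitter),
                                  nrow(targets), d)
    }
    if (n_distractors > 0) {
      lat <- matrix(rnorm(n_distractors * k), n_distractors, k)
      distract <- lat %*% t(A) +
        matrix(rnorm(n_distractors * d, sd = distractor_spread),
               n_distractors, d)
    } else {
      distract <- matrix(0, 0, d)
    }
    emb <- rbind(targets, distract)
    ids <- c(sprintf("para_%s", scenes$scene_ids),
             sprintf("distractor_%05d", seq_len(n_distractors)))
    scene_id <- c(scenes$scene_ids, rep(NA_character_, n_distractors))
    perm <- sample.int(nrow(emb))
    structure(
      list(entry_ids = ids[perm], texts = ids[perm],
           embeddings = emb[perm, , drop = FALSE],
           scene_id = scene_id[perm]),
      seed = seed, class = "caption_dictionary"
    )
  })
}

#' @export
print.caption_dictionary <- function(x, ...) {
  cat(sprintf("<caption_dictionary> %d entries (%d paraphrases, %d distractors), d = %d\n",
              length(x$entry_ids), sum(!is.na(x$scene_id)),
              sum(is.na(x$scene_id)), ncol(x$embeddings)))
  invisible(x)
}
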