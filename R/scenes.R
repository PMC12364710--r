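#' Generate a synthetic scene set with caption embeddings and category labels
#'
#' Emulates the stimulus-side structure of a natural-scenes experiment: each
#' scene has a low-dimensional latent content vector, a "true" sentence
#' embedding obtained by a fixed linear map of that latent, several caption
#' embeddings jittered around the true embedding (inter-rater variability),
#' binary multi-hot category labels derived from thresholded linear readouts
#' of the latent (so categories are linearly decodable from embeddings by
#' construction), and word-level vector surrogates tagged as nouns or verbs.
#' Noun vectors carry the scene latent through their own linear map; verb
#' vectors are latent-free noise, giving the part-of-speech feature models a
#' ground-truth asymmetry to detect.
#'
#' @param n_scenes Number of scenes.
#' @param k Latent dimension (`k <= d`).
#' @param d Embedding dimension.
#' @param n_captions Captions per scene (>= 2; 5 matches the common
#'   crowd-sourced caption sets).
#' @param caption_noise Standard deviation of the iid Gaussian jitter added to
#'   the true embedding for each caption.
#' @param m Number of binary categories.
#' @param seed Integer seed; output is bit-identical for identical seeds.
#' @param d_w Word-vector dimension (defaults to `d`).
#' @param words_per_caption Number of word surrogates per caption (split
#'   between nouns and verbs).
#' @param word_noise Sd of jitter on noun word vectors around their
#'   latent-mapped value.
#'
#' @return A `scene_set` object: list with `scene_ids`, `latent`
#'   (`n_scenes x k`), `caption_embeddings` (array `n_scenes x n_captions x
#'   d`), `mean_embedding` (arithmetic mean over captions), `true_embedding`,
#'   `categories` (binary `n_scenes x m`), `word_vectors` (nested per-scene /
#'   per-caption lists with `vectors` and `tags`), and the generative maps as
#'   attributes.
#' @export
#' @examples
#' sc <- make_scenes(20, k = 4, d = 16, n_captions = 5,
#'                   caption_noise = 0.3, m = 6, seed = 1)
#' dim(sc$mean_embedding)
make_scenes <- function(n_scenes, k, d, n_captions = 5L, caption_noise = 0.3,
                        m = 8L, seed = 1L, d_w = d, words_per_caption = 4L,
                        word_noise = 0.5) {
  n_scenes <- check_count(n_scenes, "n_scenes")
  k <- check_count(k, "k")
  d <- check_count(d, "d")
  d_w <- check_count(d_w, "d_w")
  n_captions <- check_count(n_captions, "n_captions", min = 2L)
  m <- check_count(m, "m")
  caption_noise <- check_number(caption_noise, "caption_noise", min = 0)
  words_per_caption <- check_count(words_per_caption, "words_per_caption",
                                   min = 2L)
  if (k > d) abort("`k` must not exceed `d`.")

  with_seed(derive_seed(seed, "scenes"), {
    # fixed latent -> embedding map: random semi-orthogonal, scaled so each
    # embedding dimension has unit variance; orthogonality keeps the
    # stimulus covariance well conditioned, so no embedding direction is
    # drowned by caption jitter
    A <- qr.Q(qr(matrix(rnorm(d * k), d, k))) * sqrt(d / k)
    latent <- matrix(rnorm(n_scenes * k), n_scenes, k)
    true_embedding <- latent %*% t(A)

    caption_embeddings <- array(
      rep(true_embedding, n_captions),
      dim = c(n_scenes, d, n_captions)
    )
    caption_embeddings <- aperm(caption_embeddings, c(1, 3, 2))
    if (caption_noise > 0) {
      caption_embeddings <- caption_embeddings +
        array(rnorm(length(caption_embeddings), sd = caption_noise),
              dim = dim(caption_embeddings))
    }
    mean_embedding <- apply(caption_embeddings, c(1, 3), mean)

    # categories: thresholded linear readouts of the latent; thresholds at 0
    # keep prevalence near one half per category
    V <- matrix(rnorm(k * m), k, m)
    categories <- (latent %*% V > 0) * 1L

    # word surrogates: half nouns (carry the latent), half verbs (noise)
    B_noun <- qr.Q(qr(matrix(rnorm(d_w * k), d_w, k))) * sqrt(d_w / k)
    n_nouns <- ceiling(words_per_caption / 2)
    word_vectors <- lapply(seq_len(n_scenes), function(i) {
      lapply(seq_len(n_captions), function(j) {
        nv <- matrix(rep(drop(B_noun %*% latent[i, ]), n_nouns),
                     nrow = n_nouns, byrow = TRUE) +
          matrix(rnorm(n_nouns * d_w, sd = word_noise), n_nouns, d_w)
        vv <- matrix(rnorm((words_per_caption - n_nouns) * d_w), ncol = d_w)
        list(vectors = rbind(nv, vv),
             tags = c(rep("noun", n_nouns),
                      rep("verb", words_per_caption - n_nouns)))
      })
    })

    scene_ids <- sprintf("scene_%04d", seq_len(n_scenes))
    structure(
      list(scene_ids = scene_ids, latent = latent,
           caption_embeddings = caption_embeddings,
           mean_embedding = mean_embedding,
           true_embedding = true_embedding,
           categories = categories,
           word_vectors = word_vectors),
      latent_map = A, word_map = B_noun, category_map = V,
      caption_noise = caption_noise, seed = seed,
      class = "scene_set"
    )
  })
}

#' @export
print.scene_set <- function(x, ...) {
  cat(sprintf(
    "<scene_set> %d scenes, latent dim %d, embedding dim %d, %d captions, %d categories\n",
    length(x$scene_ids), ncol(x$latent), ncol(x$mean_embedding),
    dim(x$caption_embeddings)[2], ncol(x$categories)))
  invisible(x)
}

#' Subset a scene set to a set of scene ids
#'
#' @param scenes A `scene_set`.
#' @param ids Character vector of scene ids to keep (order preserved).
#' @return A `scene_set` restricted to `ids`.
#' @export
subset_scenes <- function(scenes, ids) {
  stopifnot(inherits(scenes, "scene_set"))
  idx <- match(ids, scenes$scene_ids)
  if (anyNA(idx)) abort("Unknown scene ids requested.")
  out <- scenes
  out$scene_ids <- scenes$scene_ids[idx]
  out$latent <- scenes$latent[idx, , drop = FALSE]
  out$caption_embeddings <- scenes$caption_embeddings[idx, , , drop = FALSE]
  out$mean_embedding <- scenes$mean_embedding[idx, , drop = FALSE]
  out$true_embedding <- scenes$true_embedding[idx, , drop = FALSE]
  out$categories <- scenes$categories[idx, , drop = FALSE]
  out$word_vectors <- scenes$word_vectors[idx]
  out
}

#' @export
as_tibble.scene_set <- function(x, ...) {
  tibble(
    scene_id = x$scene_ids,
    latent = lapply(seq_along(x$scene_ids), function(i) x$latent[i, ]),
    mean_embedding = lapply(seq_along(x$scene_ids),
                            function(i) x$mean_embedding[i, ]),
    n_categories = rowSums(x$categories)
  )
}
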