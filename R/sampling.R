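#' Partition stimuli into disjoint random subsets
#'
#' Stimuli are shuffled once (seeded) and split into disjoint subsets of
#' exactly `subset_size`; a remainder that cannot fill a complete subset is
#' discarded. 10,000 stimuli at subset size 100 give 100 subsets; 6,234 give
#' 62; 5,445 give 54.
#'
#' @param ids Character vector of stimulus ids.
#' @param subset_size Number of stimuli per subset (>= 3).
#' @param seed Integer seed.
#' @return List of character vectors, each of length `subset_size`.
#' @export
sample_subsets <- function(ids, subset_size = 100L, seed = 1L) {
  subset_size <- check_count(subset_size, "subset_size", min = 3L)
  n <- length(ids)
  if (n < subset_size) {
    abort("Fewer stimuli than `subset_size`; cannot form a subset.")
  }
  n_splits <- n %/% subset_size
  with_seed(derive_seed(seed, "subsets"), {
    ord <- sample(ids)
    lapply(seq_len(n_splits), function(i) {
      ord[((i - 1L) * subset_size + 1L):(i * subset_size)]
    })
  })
}

# resolve a model argument into a per-subset rdm
model_subset_rdm <- function(model, subset) {
  if (inherits(model, "rdm")) {
    subset_rdm(model, subset)
  } else {
    compute_rdm(model, subset = subset)
  }
}

#' Subset-sampled RSA between brain responses and a model
#'
#' The stimuli are partitioned into disjoint random subsets (see
#' [sample_subsets()]); within each subset a brain RDM and a model RDM are
#' constructed and correlated over their upper triangles; the per-subset
#' correlations are averaged on the raw r scale (no Fisher transform). With
#' `subset_size` equal to the number of stimuli this reduces exactly to the
#' single full-RDM correlation.
#'
#' @param responses An `avg_responses`.
#' @param model A full `rdm`, a `feature_matrix`, or a plain feature matrix
#'   with stimulus rownames covering the response stimuli.
#' @param subset_size Stimuli per subset (default 100).
#' @param seed Integer seed for the partition.
#' @param subsets Optional precomputed partition (list of id vectors), e.g.
#'   to reuse an identical partition across models or searchlight spheres.
#' @return A `sampled_rsa` object: list with `mean_r`, `n_splits`, and
#'   `split_r` (per-subset correlations).
#' @export
sampled_rsa <- function(responses, model, subset_size = 100L, seed = 1L,
                        subsets = NULL) {
  stopifnot(inherits(responses, "avg_responses"))
  if (is.null(subsets)) {
    subsets <- sample_subsets(responses$stimulus_ids, subset_size, seed)
  }
  split_r <- vapply(subsets, function(ss) {
    brain <- compute_rdm(responses, subset = ss)
    rdm_correlation(brain, model_subset_rdm(model, ss))
  }, numeric(1))
  structure(list(mean_r = mean(split_r), n_splits = length(subsets),
                 split_r = split_r),
            class = "sampled_rsa")
}

#' @export
print.sampled_rsa <- function(x, ...) {
  cat(sprintf("<sampled_rsa> mean r = %.4f over %d splits\n",
              x$mean_r, x$n_splits))
  invisible(x)
}
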