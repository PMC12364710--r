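#' Representational dissimilarity matrix from response patterns
#'
#' Dissimilarity between two stimuli is the Pearson correlation distance
#' `1 - r` between their activity patterns across voxels (equivalently,
#' across feature dimensions for model RDMs). The result is symmetric with a
#' zero diagonal and entries in `[0, 2]`.
#'
#' A pattern with zero variance across voxels has undefined correlations; its
#' off-diagonal distances are set to the neutral value 1 with a warning.
#'
#' @param responses An `avg_responses`, `feature_matrix`, or plain matrix
#'   (`n_stimuli x p`) with row ids.
#' @param subset Optional stimulus ids to restrict to (order preserved).
#' @return An `rdm` object: list with `values` (`n x n`) and `stimulus_ids`.
#' @export
#' @examples
#' x <- avg_responses(matrix(rnorm(50), 5, 10), paste0("s", 1:5))
#' r <- compute_rdm(x)
#' all(abs(r$values - t(r$values)) < 1e-12)
compute_rdm <- function(responses, subset = NULL) {
  if (inherits(responses, "avg_responses")) {
    values <- responses$values
    ids <- responses$stimulus_ids
  } else if (inherits(responses, "feature_matrix")) {
    values <- responses$values
    ids <- responses$stimulus_ids
  } else {
    values <- as.matrix(responses)
    ids <- rownames(values)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(values)))
  }
  if (!is.null(subset)) {
    idx <- match(subset, ids)
    if (anyNA(idx)) abort("`subset` contains unknown stimulus ids.")
    values <- values[idx, , drop = FALSE]
    ids <- ids[idx]
  }
  if (nrow(values) < 3L) abort("At least 3 stimuli are required for an RDM.")
  if (ncol(values) < 2L) abort("At least 2 voxels/features are required.")

  sds <- apply(values, 1, sd)
  degenerate <- sds == 0
  cmat <- suppressWarnings(cor(t(values)))
  dist <- 1 - cmat
  if (any(degenerate)) {
    warn(sprintf("%d zero-variance pattern(s); their distances set to 1.",
                 sum(degenerate)))
    dist[degenerate, ] <- 1
    dist[, degenerate] <- 1
  }
  diag(dist) <- 0
  dist <- (dist + t(dist)) / 2
  dist <- pmin(pmax(dist, 0), 2)
  dimnames(dist) <- list(ids, ids)
  structure(list(values = dist, stimulus_ids = ids), class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %d x %d Pearson-distance matrix\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Subset an RDM to a set of stimulus ids
#'
#' @param rdm An `rdm`.
#' @param ids Stimulus ids to keep, in order.
#' @return An `rdm` over `ids`.
#' @export
subset_rdm <- function(rdm, ids) {
  stopifnot(inherits(rdm, "rdm"))
  idx <- match(ids, rdm$stimulus_ids)
  if (anyNA(idx)) abort("Unknown stimulus ids in RDM subset.")
  structure(list(values = rdm$values[idx, idx, drop = FALSE],
                 stimulus_ids = rdm$stimulus_ids[idx]),
            class = "rdm")
}

#' Correlate two RDMs over their upper triangles
#'
#' Pearson correlation of the upper-triangular vectors (diagonal excluded) of
#' two RDMs over the same stimuli in the same order. For 100 stimuli the
#' vectors have length 4,950.
#'
#' @param a,b `rdm` objects with identical stimulus ids.
#' @return A single Pearson correlation.
#' @export
rdm_correlation <- function(a, b) {
  stopifnot(inherits(a, "rdm"), inherits(b, "rdm"))
  if (!identical(a$stimulus_ids, b$stimulus_ids)) {
    abort("RDMs must cover the same stimuli in the same order.")
  }
  cor(upper_tri_vec(a$values), upper_tri_vec(b$values))
}

#' @export
as_tibble.rdm <- function(x, ...) {
  n <- length(x$stimulus_ids)
  ut <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble(stimulus_a = x$stimulus_ids[ut[, 1]],
         stimulus_b = x$stimulus_ids[ut[, 2]],
         distance = x$values[ut])
}
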