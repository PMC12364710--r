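#' Average responses container
#'
#' @param values Matrix `n_stimuli x p_voxels`.
#' @param stimulus_ids Character vector, one id per row.
#' @return An `avg_responses` object.
#' @export
avg_responses <- function(values, stimulus_ids) {
  values <- as.matrix(values)
  stopifnot(length(stimulus_ids) == nrow(values))
  if (anyNA(values) || any(!is.finite(values))) {
    abort("Average responses must be finite.")
  }
  structure(list(values = values, stimulus_ids = as.character(stimulus_ids)),
            class = "avg_responses")
}

#' @export
print.avg_responses <- function(x, ...) {
  cat(sprintf("<avg_responses> %d stimuli x %d voxels\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Standardize and average trial-level betas per stimulus
#'
#' Implements the standard beta preprocessing: per voxel, trials are z-scored
#' across single trials within each scanning session (removing session gain
#' and offset); stimuli that do not reach the full repetition count are
#' dropped; the remaining repetitions are averaged to one response pattern
#' per stimulus.
#'
#' A voxel that is constant within a session has an undefined z-score; its
#' values for that session are set to 0 and a warning is issued. A session
#' containing a single trial is an error (its sd is undefined for every
#' voxel).
#'
#' @param trials A `trial_responses` object.
#' @param n_reps Required repetition count; defaults to the design's
#'   `n_reps`.
#' @return An `avg_responses` with one row per retained stimulus.
#' @export
preprocess_betas <- function(trials, n_reps = NULL) {
  stopifnot(inherits(trials, "trial_responses"))
  if (is.null(n_reps)) n_reps <- trials$n_reps
  n_reps <- check_count(n_reps, "n_reps")

  betas <- trials$betas
  z <- betas
  n_const <- 0L
  for (s in unique(trials$session_id)) {
    rows <- which(trials$session_id == s)
    if (length(rows) < 2L) {
      abort(sprintf("Session %s has a single trial; z-scoring is undefined.",
                    s))
    }
    block <- betas[rows, , drop = FALSE]
    mu <- colMeans(block)
    sds <- apply(block, 2, sd)
    const <- sds == 0
    n_const <- n_const + sum(const)
    sds[const] <- 1
    zb <- sweep(sweep(block, 2, mu), 2, sds, "/")
    zb[, const] <- 0
    z[rows, ] <- zb
  }
  if (n_const > 0) {
    warn(sprintf(
      "%d constant voxel-session blocks; their z-scores were set to 0.",
      n_const))
  }

  counts <- table(trials$stimulus_id)
  keep_ids <- names(counts)[counts == n_reps]
  # preserve first-appearance order of stimuli
  keep_ids <- unique(trials$stimulus_id)[unique(trials$stimulus_id) %in%
                                           keep_ids]
  if (!length(keep_ids)) abort("No stimulus has the full repetition count.")

  out <- matrix(0, length(keep_ids), ncol(betas))
  grp <- match(trials$stimulus_id, keep_ids)
  ok <- !is.na(grp)
  out <- rowsum(z[ok, , drop = FALSE], grp[ok]) / n_reps
  out <- out[order(as.integer(rownames(out))), , drop = FALSE]
  rownames(out) <- NULL
  avg_responses(out, keep_ids)
}
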