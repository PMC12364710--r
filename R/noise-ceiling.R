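#' Leave-one-participant-out RSA noise ceiling
#'
#' For each participant, the ceiling is the Pearson correlation between the
#' upper triangle of that participant's RDM on the shared stimuli and the
#' element-wise mean of the other participants' RDMs on the same stimuli.
#' Intuitively the model is pitted against the average of the remaining
#' humans: a model matching a participant as well as that average has reached
#' the ceiling.
#'
#' @param responses List of `avg_responses`, one per participant, all covering
#'   the same shared stimuli in the same order (see [cohort_responses()]).
#' @param voxels Optional voxel subset (indices) applied to every participant,
#'   e.g. an ROI.
#' @return A tibble with `participant` and `ceiling`.
#' @export
rsa_noise_ceiling <- function(responses, voxels = NULL) {
  if (length(responses) < 3L) {
    abort("At least 3 participants are required for a noise ceiling.")
  }
  ids <- responses[[1]]$stimulus_ids
  for (r in responses) {
    if (!identical(r$stimulus_ids, ids)) {
      abort("All participants must share the same stimuli in the same order.")
    }
  }
  rdms <- lapply(responses, function(r) {
    v <- r$values
    if (!is.null(voxels)) v <- v[, voxels, drop = FALSE]
    compute_rdm(avg_responses(v, ids))$values
  })
  ut <- upper.tri(rdms[[1]])
  tri <- vapply(rdms, function(m) m[ut], numeric(sum(ut)))
  ceilings <- vapply(seq_along(rdms), function(i) {
    others <- rowMeans(tri[, -i, drop = FALSE])
    cor(tri[, i], others)
  }, numeric(1))
  tibble(participant = seq_along(rdms), ceiling = ceilings)
}
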