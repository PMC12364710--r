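#' Generate a synthetic multi-participant cohort
#'
#' All participants share the grid geometry, region layout and a scene pool in
#' which `n_shared` scenes are seen by everyone and each participant
#' additionally sees `n_unique` scenes that no other participant sees
#' (mirroring designs where a special image set is shared across participants
#' and the rest are mutually exclusive). Each participant's ground-truth
#' weights are the base model's weights plus iid Gaussian jitter on in-brain
#' voxels, modelling idiosyncratic functional anatomy.
#'
#' @param n_participants Number of participants (>= 2).
#' @param n_shared Number of scenes shared by all participants.
#' @param n_unique Number of participant-unique scenes each.
#' @param participant_weight_jitter Sd of the per-participant jitter added to
#'   the ground-truth weights (0 = identical brains).
#' @param grid_shape,regions,d,noise_sd,leakage Passed to
#'   [build_brain_model()].
#' @param k,n_captions,caption_noise,m Passed to [make_scenes()].
#' @param n_reps,n_sessions,gain_range,offset_range Passed to
#'   [simulate_trial_responses()].
#' @param snr If not `NULL`, overrides `noise_sd` with the per-voxel sd
#'   achieving this signal-to-noise variance ratio (see [noise_sd_for_snr()]).
#' @param seed Integer global seed; all components derive child seeds from it.
#'
#' @return A `cohort`: list with `scenes` (the full pool), `base_brain`,
#'   `participants` (each a list with `brain`, `trials`, `stimulus_ids`),
#'   `shared_ids`, `unique_ids` (list per participant).
#' @export
make_cohort <- function(n_participants = 8L, n_shared = 100L, n_unique = 200L,
                        participant_weight_jitter = 0,
                        grid_shape = c(8L, 6L, 4L), regions = NULL,
                        d = 16L, k = 6L, n_captions = 5L, caption_noise = 0.3,
                        m = 8L, noise_sd = 1, leakage = 0, snr = NULL,
                        n_reps = 3L, n_sessions = 4L,
                        gain_range = c(0.8, 1.2), offset_range = c(-0.1, 0.1),
                        seed = 1L) {
  n_participants <- check_count(n_participants, "n_participants", min = 2L)
  n_shared <- check_count(n_shared, "n_shared")
  n_unique <- check_count(n_unique, "n_unique", min = 0L)
  jit <- check_number(participant_weight_jitter, "participant_weight_jitter",
                      min = 0)

  n_pool <- n_shared + n_participants * n_unique
  scenes <- make_scenes(n_pool, k = k, d = d, n_captions = n_captions,
                        caption_noise = caption_noise, m = m,
                        seed = derive_seed(seed, "cohort_scenes"))
  if (n_unique * n_participants + n_shared > length(scenes$scene_ids)) {
    abort("Scene pool too small for the requested unique sets.")
  }

  base_brain <- build_brain_model(grid_shape, regions = regions, d = d,
                                  noise_sd = noise_sd, leakage = leakage,
                                  seed = derive_seed(seed, "cohort_brain"))
  if (!is.null(snr)) {
    base_brain$noise_sd <- noise_sd_for_snr(base_brain, scenes, snr)
  }

  shared_ids <- scenes$scene_ids[seq_len(n_shared)]
  unique_ids <- lapply(seq_len(n_participants), function(i) {
    if (n_unique == 0) return(character(0))
    start <- n_shared + (i - 1L) * n_unique
    scenes$scene_ids[(start + 1L):(start + n_unique)]
  })

  participants <- lapply(seq_len(n_participants), function(i) {
    brain_i <- base_brain
    if (jit > 0) {
      with_seed(derive_seed(seed, paste0("cohort_w", i)), {
        jmat <- matrix(rnorm(length(brain_i$W_true), sd = jit),
                       nrow(brain_i$W_true), ncol(brain_i$W_true))
        jmat[!brain_i$in_brain, ] <- 0
        brain_i$W_true <- brain_i$W_true + jmat
      })
    }
    ids_i <- c(shared_ids, unique_ids[[i]])
    trials <- simulate_trial_responses(
      brain_i, subset_scenes(scenes, ids_i), n_reps = n_reps,
      n_sessions = n_sessions, gain_range = gain_range,
      offset_range = offset_range,
      seed = derive_seed(seed, paste0("cohort_trials", i)))
    list(brain = brain_i, trials = trials, stimulus_ids = ids_i)
  })

  structure(
    list(scenes = scenes, base_brain = base_brain,
         participants = participants, shared_ids = shared_ids,
         unique_ids = unique_ids),
    seed = seed, class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants, %d shared + %d unique scenes each, %d voxels\n",
              length(x$participants), length(x$shared_ids),
              length(x$unique_ids[[1]]), nrow(x$base_brain$W_true)))
  invisible(x)
}

#' Preprocessed average responses for every participant
#'
#' Convenience wrapper: applies [preprocess_betas()] to each participant and
#' optionally restricts rows to the shared stimuli (in shared-id order).
#'
#' @param cohort A `cohort`.
#' @param shared_only If `TRUE`, keep only the shared stimuli.
#' @return List of `avg_responses`, one per participant.
#' @export
cohort_responses <- function(cohort, shared_only = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  lapply(cohort$participants, function(p) {
    avg <- preprocess_betas(p$trials)
    if (shared_only) {
      keep <- match(cohort$shared_ids, avg$stimulus_ids)
      avg_responses(avg$values[keep, , drop = FALSE], cohort$shared_ids)
    } else {
      avg
    }
  })
}
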