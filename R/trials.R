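#' Simulate trial-level voxel responses for a scene set
#'
#' Generates single-trial betas under the linear response model
#' `beta = gain_s * (W_true %*% e_i) + offset_s + noise`, where `e_i` is the
#' scene's true embedding and `gain_s`, `offset_s` are per-session scale and
#' shift drawn uniformly from the given ranges. Session effects make the
#' within-session z-scoring step of preprocessing demonstrably necessary.
#' Every scene is presented `n_reps` times; trials are assigned to sessions
#' in a seeded random order, split into contiguous blocks of near-equal size.
#'
#' @param brain A `brain_model`.
#' @param scenes A `scene_set`.
#' @param n_reps Repetitions per scene (>= 1; 3 matches typical designs).
#' @param n_sessions Number of scan sessions.
#' @param gain_range Length-2 range for session gains.
#' @param offset_range Length-2 range for session offsets.
#' @param seed Integer seed.
#' @param noise_sd Optional override of the brain model's per-voxel noise sd.
#'
#' @return A `trial_responses` object: list with `betas`
#'   (`n_trials x p_voxels`), `session_id`, `stimulus_id`, `repetition`,
#'   and `n_reps`.
#' @export
simulate_trial_responses <- function(brain, scenes, n_reps = 3L,
                                     n_sessions = 4L,
                                     gain_range = c(0.8, 1.2),
                                     offset_range = c(-0.1, 0.1),
                                     seed = 1L, noise_sd = NULL) {
  stopifnot(inherits(brain, "brain_model"), inherits(scenes, "scene_set"))
  n_reps <- check_count(n_reps, "n_reps")
  n_sessions <- check_count(n_sessions, "n_sessions")
  if (ncol(scenes$true_embedding) != ncol(brain$W_true)) {
    abort("Embedding dimension mismatch between scenes and brain model.")
  }
  if (is.null(noise_sd)) noise_sd <- brain$noise_sd
  noise_sd <- rep_len(as.numeric(noise_sd), nrow(brain$W_true))

  n_scenes <- length(scenes$scene_ids)
  n_trials <- n_scenes * n_reps
  p <- nrow(brain$W_true)
  signal <- true_responses(brain, scenes)

  with_seed(derive_seed(seed, "trials"), {
    stimulus_id <- rep(scenes$scene_ids, each = n_reps)
    repetition <- rep(seq_len(n_reps), times = n_scenes)
    ord <- sample.int(n_trials)

    # contiguous near-equal session blocks over the shuffled trial order
    block <- rep(seq_len(n_sessions),
                 diff(floor(seq(0, n_trials, length.out = n_sessions + 1))))
    session_id <- integer(n_trials)
    session_id[ord] <- block

    gains <- runif(n_sessions, gain_range[1], gain_range[2])
    offsets <- runif(n_sessions, offset_range[1], offset_range[2])

    scene_idx <- match(stimulus_id, scenes$scene_ids)
    betas <- signal[scene_idx, , drop = FALSE] * gains[session_id] +
      offsets[session_id]
    if (any(noise_sd > 0)) {
      betas <- betas + matrix(rnorm(n_trials * p), n_trials, p) *
        rep(noise_sd, each = n_trials)
    }
    rownames(betas) <- NULL

    structure(
      list(betas = betas, session_id = session_id,
           stimulus_id = stimulus_id, repetition = repetition,
           n_reps = n_reps),
      seed = seed, class = "trial_responses"
    )
  })
}

#' @export
print.trial_responses <- function(x, ...) {
  cat(sprintf("<trial_responses> %d trials (%d stimuli x %d reps), %d voxels, %d sessions\n",
              nrow(x$betas), length(unique(x$stimulus_id)), x$n_reps,
              ncol(x$betas), length(unique(x$session_id))))
  invisible(x)
}

#' @export
as_tibble.trial_responses <- function(x, ...) {
  tibble(trial = seq_len(nrow(x$betas)), stimulus_id = x$stimulus_id,
         session_id = x$session_id, repetition = x$repetition)
}
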