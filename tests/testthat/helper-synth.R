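# shared fixture builders; everything is generated in code at test time

# a trial_responses object built directly from a signal matrix, bypassing the
# generator (used to control session composition exactly)
manual_trials <- function(signal, session_id, stimulus_id, repetition,
                          n_reps = max(repetition)) {
  structure(
    list(betas = signal, session_id = session_id, stimulus_id = stimulus_id,
         repetition = repetition, n_reps = n_reps),
    class = "trial_responses")
}

# small scene set + brain + trials in one call
tiny_world <- function(n_scenes = 40, k = 4, d = 12, grid = c(6, 4, 3),
                       noise_sd = 0.3, caption_noise = 0.2, seed = 1,
                       n_sessions = 2, gain_range = c(0.8, 1.2),
                       offset_range = c(-0.1, 0.1), leakage = 0) {
  scenes <- make_scenes(n_scenes, k = k, d = d, n_captions = 5,
                        caption_noise = caption_noise, m = 6, seed = seed)
  brain <- build_brain_model(grid, d = d, noise_sd = noise_sd,
                             leakage = leakage, seed = seed + 1)
  trials <- simulate_trial_responses(brain, scenes, n_reps = 3,
                                     n_sessions = n_sessions,
                                     gain_range = gain_range,
                                     offset_range = offset_range,
                                     seed = seed + 2)
  list(scenes = scenes, brain = brain, trials = trials)
}

# standardized noiseless responses wrapped as a feature matrix (the
# generative-truth model in feature form, usable with sampled_rsa)
truth_features <- function(brain, scenes, voxels = NULL) {
  r <- true_responses(brain, scenes)
  if (is.null(voxels)) voxels <- which(as.vector(brain$in_brain))
  r <- scale(r[, voxels, drop = FALSE])
  r[is.na(r)] <- 0
  feature_matrix(r, "truth", scenes$scene_ids)
}

# from-definition Benjamini-Hochberg step-up (independent oracle)
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# brute-force sphere membership by triple loop over the whole grid
brute_sphere <- function(mask, center_xyz, radius) {
  dims <- dim(mask)
  members <- integer(0)
  total <- 0L
  inside <- 0L
  r <- floor(radius)
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    if (dx^2 + dy^2 + dz^2 > radius^2) next
    total <- total + 1L
    x <- center_xyz[1] + dx; y <- center_xyz[2] + dy; z <- center_xyz[3] + dz
    if (x >= 1 && x <= dims[1] && y >= 1 && y <= dims[2] &&
        z >= 1 && z <= dims[3] && mask[x, y, z]) {
      inside <- inside + 1L
      members <- c(members, (z - 1L) * dims[1] * dims[2] +
                     (y - 1L) * dims[1] + x)
    }
  }
  list(members = sort(members), fraction = inside / total)
}
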