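test_that("make_scenes honours the zero-noise and determinism contracts", {
  sc <- make_scenes(10, k = 3, d = 8, n_captions = 5, caption_noise = 0,
                    m = 4, seed = 7)
  for (j in 1:5) {
    expect_equal(sc$caption_embeddings[, j, ], sc$true_embedding)
  }
  expect_equal(sc$mean_embedding, sc$true_embedding)

  sc2 <- make_scenes(10, k = 3, d = 8, n_captions = 5, caption_noise = 0,
                     m = 4, seed = 7)
  expect_identical(sc, sc2)

  sc3 <- make_scenes(10, k = 3, d = 8, n_captions = 5, caption_noise = 0.5,
                     m = 4, seed = 8)
  expect_true(all(sc3$categories %in% c(0L, 1L)))
  expect_equal(sc3$mean_embedding,
               apply(sc3$caption_embeddings, c(1, 3), mean),
               tolerance = 1e-10)

  expect_error(make_scenes(0, k = 3, d = 8), "n_scenes")
  expect_error(make_scenes(10, k = 9, d = 8), "k")
  expect_error(make_scenes(10, k = 3, d = 8, n_captions = 1), "n_captions")
  expect_error(make_scenes(10, k = 3, d = 8, caption_noise = -1),
               "caption_noise")
})

test_that("caption-mean error matches the sigma * sqrt(d/5) closed form", {
  # mean of n_captions iid jitters has per-dim sd sigma/sqrt(5); the error
  # norm over d dims concentrates around sigma * sqrt(d/5)
  sigma <- 0.5
  d <- 16
  sc <- make_scenes(1000, k = 8, d = d, n_captions = 5,
                    caption_noise = sigma, m = 4, seed = 11)
  err <- sqrt(rowSums((sc$mean_embedding - sc$true_embedding)^2))
  expect_equal(mean(err), sigma * sqrt(d / 5), tolerance = 0.05)
})

test_that("brain model respects region support, mask and shape", {
  regions <- list(
    list(name = "a", voxels = 1:20, dims = 1:2),
    list(name = "b", voxels = 21:40, dims = 3:4))
  br <- build_brain_model(c(4, 5, 2), regions = regions, d = 6,
                          leakage = 0, seed = 3)
  expect_true(all(br$W_true[1:20, 3:6] == 0))
  expect_true(all(br$W_true[21:40, c(1:2, 5:6)] == 0))
  expect_true(all(br$W_true[!br$in_brain, ] == 0))

  full <- build_brain_model(c(10, 10, 10), d = 8, seed = 4)
  expect_equal(nrow(full$W_true), 1000L)
  expect_true(all(full$in_brain))

  overlap <- list(
    list(name = "a", voxels = 1:20, dims = 1:2),
    list(name = "b", voxels = 15:30, dims = 3:4))
  expect_error(build_brain_model(c(4, 5, 2), regions = overlap, d = 6),
               "disjoint")
})

test_that("orthogonal-subspace regions give uncorrelated ground-truth RDMs", {
  sc <- make_scenes(50, k = 8, d = 8, n_captions = 5, caption_noise = 0,
                    m = 4, seed = 5)
  # the latent->embedding map mixes dimensions, so replace the embeddings
  # with independent coordinates: the two dimension blocks then carry
  # genuinely independent structure
  set.seed(50)
  sc$true_embedding <- matrix(rnorm(50 * 8), 50, 8)
  regions <- list(
    list(name = "a", voxels = 1:30, dims = 1:4),
    list(name = "b", voxels = 31:60, dims = 5:8))
  br <- build_brain_model(c(6, 5, 2), regions = regions, d = 8,
                          leakage = 0, seed = 6)
  resp <- true_responses(br, sc)
  rdm_a <- compute_rdm(avg_responses(resp[, 1:30], sc$scene_ids))
  rdm_b <- compute_rdm(avg_responses(resp[, 31:60], sc$scene_ids))
  expect_lt(abs(rdm_correlation(rdm_a, rdm_b)), 0.15)
})

test_that("trial simulation satisfies the noiseless and count contracts", {
  sc <- make_scenes(100, k = 4, d = 10, n_captions = 5, caption_noise = 0,
                    m = 4, seed = 2)
  br <- build_brain_model(c(5, 4, 2), d = 10, noise_sd = 0, seed = 3)
  tr <- simulate_trial_responses(br, sc, n_reps = 3, n_sessions = 3,
                                 gain_range = c(1, 1),
                                 offset_range = c(0, 0), seed = 4)
  expect_equal(nrow(tr$betas), 300L)
  sig <- true_responses(br, sc)
  for (i in c(1, 50, 100)) {
    reps <- tr$betas[tr$stimulus_id == sc$scene_ids[i], , drop = FALSE]
    expect_equal(nrow(reps), 3L)
    for (j in 1:3) expect_equal(unname(reps[j, ]), unname(sig[i, ]))
  }
  # session partition covers each trial exactly once
  expect_equal(sort(unique(tr$session_id)), 1:3)
  expect_equal(length(tr$session_id), 300L)

  bad <- make_scenes(10, k = 4, d = 9, n_captions = 5, seed = 2)
  expect_error(simulate_trial_responses(br, bad), "mismatch")
})

test_that("repetition variance matches the injected noise variance", {
  sc <- make_scenes(500, k = 4, d = 10, n_captions = 5, caption_noise = 0,
                    m = 4, seed = 12)
  br <- build_brain_model(c(5, 4, 2), d = 10, noise_sd = 0.7, seed = 13)
  tr <- simulate_trial_responses(br, sc, n_reps = 3, n_sessions = 1,
                                 gain_range = c(1, 1),
                                 offset_range = c(0, 0), seed = 14)
  grp <- match(tr$stimulus_id, sc$scene_ids)
  v <- sapply(seq_len(ncol(tr$betas)), function(vx) {
    mean(tapply(tr$betas[, vx], grp, var))
  })
  expect_equal(mean(v), 0.7^2, tolerance = 0.02)
})

test_that("caption dictionary contains targets plus distractors, reproducibly", {
  sc <- make_scenes(100, k = 4, d = 12, n_captions = 5, caption_noise = 0.2,
                    m = 4, seed = 21)
  dict0 <- build_caption_dictionary(sc, n_distractors = 0,
                                    paraphrase_jitter = 0, seed = 22)
  expect_equal(length(dict0$entry_ids), 100L)
  ord <- match(sc$scene_ids, dict0$scene_id)
  expect_equal(unname(dict0$embeddings[ord, ]), unname(sc$true_embedding))
  # lookup of any true embedding returns its own entry
  hits <- dictionary_lookup(sc$true_embedding, dict0)
  expect_equal(dict0$scene_id[hits$best_entry], sc$scene_ids)

  dict <- build_caption_dictionary(sc, n_distractors = 900, seed = 23)
  expect_equal(length(dict$entry_ids), 1000L)
  expect_identical(dict, build_caption_dictionary(sc, n_distractors = 900,
                                                  seed = 23))
})

test_that("widely spread distractors score below the paraphrase entry", {
  sc <- make_scenes(60, k = 4, d = 16, n_captions = 5, caption_noise = 0.2,
                    m = 4, seed = 31)
  dict <- build_caption_dictionary(sc, n_distractors = 300,
                                   distractor_spread = 3,
                                   paraphrase_jitter = 0.1, seed = 32)
  is_para <- !is.na(dict$scene_id)
  para_r <- numeric(60)
  best_distract_r <- numeric(60)
  for (i in 1:60) {
    rs <- apply(dict$embeddings, 1, cor, y = sc$true_embedding[i, ])
    para_r[i] <- rs[is_para & dict$scene_id == sc$scene_ids[i]]
    best_distract_r[i] <- max(rs[!is_para])
  }
  expect_gt(mean(para_r), mean(best_distract_r))
})

test_that("cohort structure: shared stimuli, exclusivity, jitter-free identity", {
  ch <- make_cohort(n_participants = 3, n_shared = 20, n_unique = 10,
                    participant_weight_jitter = 0, grid_shape = c(4, 3, 2),
                    d = 8, k = 3, caption_noise = 0, noise_sd = 0,
                    gain_range = c(1, 1), offset_range = c(0, 0),
                    n_sessions = 1, seed = 41)
  for (p in ch$participants) {
    expect_true(all(ch$shared_ids %in% p$stimulus_ids))
  }
  uni <- unlist(ch$unique_ids)
  expect_equal(anyDuplicated(uni), 0L)
  expect_true(!any(uni %in% ch$shared_ids))

  # with no jitter and no noise, averaged raw responses to the shared
  # stimuli are identical across participants
  raw_shared <- lapply(ch$participants, function(p) {
    t(vapply(ch$shared_ids, function(id) {
      colMeans(p$trials$betas[p$trials$stimulus_id == id, , drop = FALSE])
    }, numeric(ncol(p$trials$betas))))
  })
  expect_equal(raw_shared[[1]], raw_shared[[2]], tolerance = 1e-12)
  expect_equal(raw_shared[[2]], raw_shared[[3]], tolerance = 1e-12)
})
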