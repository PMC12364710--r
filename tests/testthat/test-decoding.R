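test_that("a noiseless invertible generative map is decoded exactly", {
  sc <- make_scenes(80, k = 6, d = 10, n_captions = 5, caption_noise = 0,
                    m = 4, seed = 1)
  br <- build_brain_model(c(5, 4, 2), d = 10, noise_sd = 0, seed = 2)
  tr <- simulate_trial_responses(br, sc, n_sessions = 1,
                                 gain_range = c(1, 1),
                                 offset_range = c(0, 0), seed = 3)
  avg <- preprocess_betas(tr)
  idx_tr <- 1:60
  idx_te <- 61:80
  suppressWarnings(
    dm <- fit_decoding_model(avg$values[idx_tr, ],
                             sc$mean_embedding[idx_tr, ], seed = 4))
  expect_equal(length(dm$fractions), 20L)
  pred <- predict(dm, avg$values[idx_te, ])
  scores <- prediction_score(pred, sc$mean_embedding[idx_te, ])
  expect_true(all(scores > 0.999))
})

test_that("shuffled training pairings null the decoder", {
  sc <- make_scenes(100, k = 6, d = 10, n_captions = 5, caption_noise = 0,
                    m = 4, seed = 5)
  br <- build_brain_model(c(5, 4, 2), d = 10, noise_sd = 0.5, seed = 6)
  tr <- simulate_trial_responses(br, sc, n_sessions = 2, seed = 7)
  avg <- preprocess_betas(tr)
  idx_tr <- 1:70
  set.seed(8)
  perm <- sample(idx_tr)
  suppressWarnings(
    dm <- fit_decoding_model(avg$values[idx_tr, ],
                             sc$mean_embedding[perm, ], seed = 9))
  pred <- predict(dm, avg$values[71:100, ])
  scores <- prediction_score(pred, sc$mean_embedding[71:100, ])
  expect_lt(abs(mean(scores)), 0.2)
})

test_that("prediction_score anchors and null distribution", {
  v <- rnorm(20)
  expect_equal(prediction_score(v, v), 1)
  expect_equal(prediction_score(-(v - mean(v)), v - mean(v)), -1)
  expect_true(is.na(prediction_score(rep(1, 20), v)))

  set.seed(10)
  d <- 768
  rs <- prediction_score(matrix(rnorm(200 * d), 200, d),
                         matrix(rnorm(200 * d), 200, d))
  expect_lt(abs(mean(rs)), 0.02)
  expect_equal(sd(rs), 1 / sqrt(d - 1), tolerance = 0.15)
})

test_that("caption noise ceiling follows inter-caption consistency", {
  sc0 <- make_scenes(20, k = 4, d = 12, n_captions = 5, caption_noise = 0,
                     m = 4, seed = 11)
  nc0 <- caption_noise_ceiling(sc0)
  expect_equal(nc0$ceiling, rep(1, 20), tolerance = 1e-10)

  ceilings <- vapply(c(0.2, 0.7, 2), function(cn) {
    sc <- make_scenes(50, k = 4, d = 12, n_captions = 5, caption_noise = cn,
                      m = 4, seed = 12)
    mean(caption_noise_ceiling(sc)$ceiling)
  }, numeric(1))
  expect_true(all(diff(ceilings) < 0))

  set.seed(13)
  indep <- array(rnorm(50 * 5 * 12), c(50, 5, 12))
  expect_lt(abs(mean(caption_noise_ceiling(indep)$ceiling)), 0.1)

  expect_error(caption_noise_ceiling(array(rnorm(40), c(10, 2, 2))),
               "3 captions")
})

test_that("dictionary lookup is exact, scale-invariant and block-independent", {
  sc <- make_scenes(40, k = 4, d = 12, n_captions = 5, caption_noise = 0.2,
                    m = 4, seed = 14)
  dict <- build_caption_dictionary(sc, n_distractors = 160, seed = 15)
  pred <- sc$true_embedding + matrix(rnorm(40 * 12, sd = 0.05), 40, 12)

  hit <- dictionary_lookup(pred, dict)
  # block size must not change results
  for (bs in c(1, 7, 50)) {
    expect_equal(dictionary_lookup(pred, dict, block_size = bs), hit)
  }
  # positive rescaling must not change the retrieved entries
  expect_equal(dictionary_lookup(5 * pred, dict)$best_entry, hit$best_entry)

  # exact embedding retrieves its own paraphrase
  exact <- dictionary_lookup(sc$true_embedding, dict)
  expect_equal(dict$scene_id[exact$best_entry], sc$scene_ids)

  # ties break to the lowest entry index
  emb <- rbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1))
  expect_equal(dictionary_lookup(c(1, 2, 3), emb)$best_entry, 1L)
  expect_error(dictionary_lookup(c(1, 1, 1), matrix(1, 3, 3)), "constant")
})

test_that("retrieval accuracy declines as distractors accumulate", {
  sc <- make_scenes(40, k = 4, d = 12, n_captions = 5, caption_noise = 0.2,
                    m = 4, seed = 16)
  acc <- sapply(c(0, 200, 2000), function(nd) {
    mean(vapply(1:5, function(s) {
      set.seed(100 + s)
      pred <- sc$true_embedding + matrix(rnorm(40 * 12, sd = 0.6), 40, 12)
      dict <- build_caption_dictionary(sc, n_distractors = nd,
                                       distractor_spread = 0.2, seed = s)
      hit <- dictionary_lookup(pred, dict)
      ret <- dict$scene_id[hit$best_entry]
      mean(!is.na(ret) & ret == sc$scene_ids)  # distractor hits are misses
    }, numeric(1)))
  })
  expect_true(all(diff(acc) < 0))
})

test_that("ranks order scores descending with index tie-breaks", {
  expect_equal(rank_predictions(c(0.9, 0.1, 0.5)), c(0L, 2L, 1L))
  expect_equal(rank_predictions(rep(0.3, 4)), 0:3)
  set.seed(17)
  scores <- rnorm(515)
  rk <- rank_predictions(scores)
  expect_equal(sort(rk), 0:514)
  expect_equal(max(rk), 514L)
  expect_equal(which(rk == 0L), which.max(scores))
  expect_error(rank_predictions(numeric(0)), "non-empty")
})

test_that("decode_lookup ties the pipeline together", {
  sc <- make_scenes(60, k = 4, d = 12, n_captions = 5, caption_noise = 0.1,
                    m = 4, seed = 18)
  br <- build_brain_model(c(5, 4, 2), d = 12, noise_sd = 0.2, seed = 19)
  tr <- simulate_trial_responses(br, sc, n_sessions = 2, seed = 20)
  avg <- preprocess_betas(tr)
  suppressWarnings(
    dm <- fit_decoding_model(avg$values[1:45, ], sc$mean_embedding[1:45, ],
                             seed = 21))
  dict <- build_caption_dictionary(sc, n_distractors = 100, seed = 22)
  test_avg <- avg_responses(avg$values[46:60, ], avg$stimulus_ids[46:60])
  res <- decode_lookup(dm, test_avg, sc$mean_embedding[46:60, ], dict)
  expect_equal(sort(res$rank), 0:14)
  expect_equal(res$stimulus_id, sc$scene_ids[46:60])
  expect_true(mean(res$retrieved_scene == res$stimulus_id, na.rm = TRUE) > 0.5)
})

test_that("prediction scores never beat the inter-caption ceiling", {
  # when the decoded estimate is itself a single jittered caption, its score
  # against the caption mean is bounded by the inter-caption consistency
  sc <- make_scenes(200, k = 6, d = 16, n_captions = 5, caption_noise = 0.6,
                    m = 4, seed = 30)
  # a fresh sixth caption, jittered like the others but independent of the
  # five that define the target mean
  set.seed(31)
  pred <- sc$true_embedding +
    matrix(rnorm(length(sc$true_embedding), sd = 0.6), 200)
  scores <- prediction_score(pred, sc$mean_embedding)
  ceiling <- caption_noise_ceiling(sc)$ceiling
  expect_lt(mean(scores), mean(ceiling) + 0.05)
})
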