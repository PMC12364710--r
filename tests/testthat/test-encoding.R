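test_that("cross-validated fit recovers an exact linear map", {
  expect_equal(length(fraction_grid()), 20L)
  set.seed(7)
  n <- 100; d <- 8; p <- 15
  X <- matrix(rnorm(n * d), n, d)
  W <- matrix(rnorm(d * p), d, p)
  Y <- X %*% W
  fit <- fit_encoding_model(X, Y, seed = 1)
  for (j in 1:p) {
    expect_gt(cor(fit$coef[, j], W[, j]), 0.999)
  }
  expect_true(all(fit$best_fraction %in% fit$fractions))
  # evaluation on held-out noiseless data is perfect
  Xt <- matrix(rnorm(30 * d), 30, d)
  ev <- evaluate_encoding(fit, Xt, Xt %*% W)
  expect_equal(ev$r, rep(1, p), tolerance = 1e-6)
})

test_that("selected fractions shrink as noise grows", {
  set.seed(8)
  n <- 60; d <- 12; p <- 20
  X <- matrix(rnorm(n * d), n, d)
  W <- matrix(rnorm(d * p), d, p)
  mean_frac <- vapply(c(0.5, 2, 8), function(ns) {
    Y <- X %*% W + matrix(rnorm(n * p, sd = ns * sqrt(d)), n, p)
    fit <- fit_encoding_model(X, Y, seed = 3)
    mean(fit$best_fraction)
  }, numeric(1))
  expect_true(all(diff(mean_frac) < 0))
})

test_that("constant training targets are flagged with zero weights", {
  set.seed(9)
  X <- matrix(rnorm(40 * 5), 40, 5)
  Y <- cbind(X %*% rnorm(5), rep(2, 40))
  expect_warning(fit <- fit_encoding_model(X, Y, seed = 1), "constant")
  expect_true(fit$flagged[2])
  expect_equal(fit$coef[, 2], rep(0, 5))
  expect_equal(fit$best_fraction[2], min(fit$fractions))
  ev <- evaluate_encoding(fit, X[1:10, ], Y[1:10, ])
  expect_true(is.na(ev$r[2]))
  expect_error(evaluate_encoding(fit, X[1:2, ], Y[1:2, ]), "3 test")
})

test_that("permuted test labels null the encoding score", {
  set.seed(10)
  n <- 80; d <- 6; p <- 30
  X <- matrix(rnorm(n * d), n, d)
  W <- matrix(rnorm(d * p), d, p)
  Y <- X %*% W + matrix(rnorm(n * p, sd = 0.2), n, p)
  fit <- fit_encoding_model(X[1:60, ], Y[1:60, ], seed = 2)
  perm <- sample(61:80)
  ev <- evaluate_encoding(fit, X[61:80, ], Y[perm, ])
  expect_lt(abs(mean(ev$r)), 0.15)
})

test_that("interparticipant agreement tracks cohort structure", {
  ch <- make_cohort(n_participants = 4, n_shared = 30, n_unique = 5,
                    grid_shape = c(4, 3, 2), d = 8, k = 3, caption_noise = 0,
                    noise_sd = 0, n_sessions = 1, gain_range = c(1, 1),
                    offset_range = c(0, 0), seed = 61)
  shared <- cohort_responses(ch, shared_only = TRUE)
  agr <- interparticipant_agreement(shared)
  expect_equal(mean(agr$agreement, na.rm = TRUE), 1, tolerance = 1e-6)

  # one pure-noise participant scores near zero
  set.seed(62)
  shared[[3]] <- avg_responses(matrix(rnorm(length(shared[[3]]$values)),
                                      nrow(shared[[3]]$values)),
                               shared[[3]]$stimulus_ids)
  agr2 <- interparticipant_agreement(shared)
  noise_p <- dplyr::filter(agr2, participant == 3)
  expect_lt(abs(mean(noise_p$agreement, na.rm = TRUE)), 0.1)
  expect_error(interparticipant_agreement(shared[1]), "2 participants")
})

test_that("agreement decreases monotonically with weight jitter", {
  mean_agr <- vapply(c(0, 0.5, 2), function(j) {
    ch <- make_cohort(n_participants = 4, n_shared = 30, n_unique = 5,
                      participant_weight_jitter = j,
                      grid_shape = c(4, 3, 2), d = 8, k = 3,
                      caption_noise = 0, noise_sd = 0.2, n_sessions = 1,
                      seed = 63)
    agr <- interparticipant_agreement(cohort_responses(ch, shared_only = TRUE))
    mean(agr$agreement, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_agr) < 0))
})

test_that("cross-participant encoding generalizes exactly in a noiseless cohort", {
  ch <- make_cohort(n_participants = 3, n_shared = 20, n_unique = 40,
                    grid_shape = c(4, 3, 2), d = 6, k = 3, caption_noise = 0,
                    noise_sd = 0, n_sessions = 1, gain_range = c(1, 1),
                    offset_range = c(0, 0), seed = 71)
  resp <- cohort_responses(ch)
  shared <- cohort_responses(ch, shared_only = TRUE)
  emb <- ch$scenes$mean_embedding
  rownames(emb) <- ch$scenes$scene_ids
  models <- lapply(seq_along(resp), function(i) {
    train_ids <- ch$unique_ids[[i]]
    idx <- match(train_ids, resp[[i]]$stimulus_ids)
    fit_encoding_model(emb[train_ids, ],
                       resp[[i]]$values[idx, , drop = FALSE], seed = i)
  })
  Xs <- emb[ch$shared_ids, ]
  within <- evaluate_encoding(models[[1]], Xs, shared[[1]])
  cross <- cross_participant_encode(models, shared, Xs, train = 1, test = 2)
  expect_gt(mean(within$r, na.rm = TRUE), 0.99)
  expect_gt(mean(cross$r, na.rm = TRUE), 0.99)
  expect_error(cross_participant_encode(models, shared, Xs, 2, 2), "differ")
})

test_that("cross-participant transfer degrades with weight jitter", {
  ch <- make_cohort(n_participants = 3, n_shared = 20, n_unique = 40,
                    participant_weight_jitter = 1,
                    grid_shape = c(4, 3, 2), d = 6, k = 3, caption_noise = 0,
                    noise_sd = 0.2, n_sessions = 1, seed = 72)
  resp <- cohort_responses(ch)
  shared <- cohort_responses(ch, shared_only = TRUE)
  emb <- ch$scenes$mean_embedding
  rownames(emb) <- ch$scenes$scene_ids
  models <- lapply(seq_along(resp), function(i) {
    train_ids <- ch$unique_ids[[i]]
    idx <- match(train_ids, resp[[i]]$stimulus_ids)
    fit_encoding_model(emb[train_ids, ],
                       resp[[i]]$values[idx, , drop = FALSE], seed = i)
  })
  Xs <- emb[ch$shared_ids, ]
  within <- mean(evaluate_encoding(models[[1]], Xs, shared[[1]])$r,
                 na.rm = TRUE)
  cross <- mean(cross_participant_encode(models, shared, Xs, 1, 2)$r,
                na.rm = TRUE)
  expect_lt(cross, within)
})

test_that("sentence contrasts are antisymmetric and localize selectivity", {
  # two regions selective for disjoint embedding subspaces; sentences loading
  # on region A's dims versus region B's dims should separate the regions
  sc <- make_scenes(80, k = 8, d = 8, n_captions = 5, caption_noise = 0,
                    m = 4, seed = 81)
  diffs <- vapply(1:5, function(s) {
    br <- build_brain_model(c(6, 4, 2), d = 8, noise_sd = 0.5,
                            seed = 80 + s)
    tr <- simulate_trial_responses(br, sc, n_sessions = 2, seed = 90 + s)
    avg <- preprocess_betas(tr)
    fit <- fit_encoding_model(sc$mean_embedding, avg$values, seed = s)
    # conditions load +v versus -v along region A's subspace: the contrast
    # 2 w.v is nonzero only where weights live on dims 1:4
    v <- matrix(0, 5, 8)
    v[, 1:4] <- rnorm(20)
    ctr <- sentence_contrast(list(fit, fit), v, -v)
    reg <- br$region_id
    # ground-truth weights are signed, so localization shows as magnitude
    mean(abs(ctr$group$estimate[reg == 1])) -
      mean(abs(ctr$group$estimate[reg == 2]))
  }, numeric(1))
  expect_true(all(diffs > 0))

  # identical conditions give exactly zero; swapping negates exactly
  w <- tiny_world(n_scenes = 40, seed = 82)
  avg <- preprocess_betas(w$trials)
  fit <- fit_encoding_model(w$scenes$mean_embedding, avg$values, seed = 1)
  cond <- matrix(rnorm(5 * 12), 5, 12)
  cond2 <- matrix(rnorm(5 * 12), 5, 12)
  same <- sentence_contrast(list(fit, fit), cond, cond)
  expect_true(all(same$contrast == 0))
  expect_true(all(same$group$p == 1))
  ab <- sentence_contrast(list(fit, fit), cond, cond2)
  ba <- sentence_contrast(list(fit, fit), cond2, cond)
  expect_equal(ab$contrast, -ba$contrast)
  expect_error(sentence_contrast(list(fit), cond[, 1:5], cond2[, 1:5]),
               "dimension")
})

test_that("encoding test r respects the analytic prediction ceiling", {
  # with signal variance s2 and averaged noise variance n2, no model can beat
  # r = sqrt(s2 / (s2 + n2)) on average
  set.seed(11)
  n <- 400; d <- 10; p <- 40
  X <- matrix(rnorm(n * d), n, d)
  W <- matrix(rnorm(d * p, sd = 1 / sqrt(d)), d, p)
  noise_sd <- 0.6
  Y <- X %*% W + matrix(rnorm(n * p, sd = noise_sd), n, p)
  fit <- fit_encoding_model(X[1:300, ], Y[1:300, ], seed = 1)
  ev <- evaluate_encoding(fit, X[301:400, ], Y[301:400, ])
  s2 <- colSums(W^2)  # per-voxel signal variance for isotropic X
  ceiling_r <- sqrt(s2 / (s2 + noise_sd^2))
  expect_lt(mean(ev$r), mean(ceiling_r) + 0.03)
  expect_gt(mean(ev$r), mean(ceiling_r) - 0.1)
})
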