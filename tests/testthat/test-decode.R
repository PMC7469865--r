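test_that("trial partitioning makes equal groups and omits the remainder", {
  set.seed(1)
  cond9 <- rep("a", 9)
  a9 <- partition_trials(cond9, 3)
  expect_equal(as.integer(table(a9)), rep(3L, 3))
  expect_equal(sum(is.na(a9)), 0)
  # 10 trials -> 3/3/3 and one omitted
  a10 <- partition_trials(rep("a", 10), 3)
  expect_equal(sum(is.na(a10)), 1)
  expect_equal(as.integer(table(a10)), rep(3L, 3))
  # both conditions handled independently
  ab <- partition_trials(rep(c("a", "b"), c(7, 8)), 3)
  expect_equal(sum(is.na(ab)), 1 + 2)
  expect_error(partition_trials(rep("a", 2), 3), "fewer trials")
})

test_that("partition assignments are uniform over group patterns (enumeration check)", {
  # n = 6, k = 3: each balanced assignment should appear ~equally often
  set.seed(99)
  draws <- replicate(3000, paste(partition_trials(rep("a", 6), 3),
                                 collapse = ""))
  counts <- table(draws)
  expect_equal(length(counts), 90)  # 6! / (2!^3) = 90 balanced assignments
  chi <- suppressWarnings(chisq.test(counts))
  expect_gt(chi$p.value, 0.001)
})

test_that("pattern z-normalization follows the sample-SD convention", {
  expect_equal(znorm_pattern(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(znorm_pattern(rep(4, 5)), rep(0, 5))  # degenerate -> zeros
  v <- rnorm(8)
  expect_equal(znorm_pattern(v + 100), znorm_pattern(v))  # shift invariant
  expect_equal(sd(znorm_pattern(v)), 1)
})

test_that("group-averaged patterns are the z-scored member means", {
  set.seed(6)
  X <- matrix(rnorm(12 * 4), 12, 4)
  cond <- rep(c("a", "b"), each = 6)
  assign <- rep(rep(1:3, each = 2), 2)
  pats <- build_patterns(X, cond, assign)
  expect_equal(dim(pats$patterns), c(6, 4))
  sel <- which(cond == "b" & assign == 2)
  want <- znorm_pattern(colMeans(X[sel, ]))
  got <- pats$patterns[pats$condition == "b" & pats$group == 2, ]
  expect_equal(got, want)
})

test_that("cross-validated accuracy matches a maximum-margin oracle on a toy problem", {
  set.seed(42)
  for (rep_i in 1:8) {
    P <- matrix(rnorm(6 * 4), 6, 4)
    pats <- list(patterns = P, group = rep(1:3, 2),
                 condition = rep(c("a", "b"), each = 3))
    res <- crossval_accuracy_at_time(pats, cost = 1e6)  # near hard margin
    correct_oracle <- 0
    for (g in 1:3) {
      tr_a <- P[pats$condition == "a" & pats$group != g, , drop = FALSE]
      tr_b <- P[pats$condition == "b" & pats$group != g, , drop = FALSE]
      te <- P[pats$group == g, , drop = FALSE]
      pred <- max_margin_oracle_predict(tr_a, tr_b, te)
      correct_oracle <- correct_oracle +
        sum(pred == pats$condition[pats$group == g])
    }
    expect_equal(res$correct, correct_oracle)
    expect_equal(res$attempts, 6)
  }
})

test_that("separable patterns decode perfectly and shuffled labels sit at chance", {
  # noiseless, linearly separable: accuracy 1 at every fold
  P <- rbind(matrix(rnorm(12, mean = 3), 3, 4),
             matrix(rnorm(12, mean = -3), 3, 4))
  pats <- list(patterns = P, group = rep(1:3, 2),
               condition = rep(c("a", "b"), each = 3))
  res <- crossval_accuracy_at_time(pats)
  expect_equal(res$correct / res$attempts, 1)
  # random labels: long-run mean accuracy ~ 0.5
  set.seed(11)
  accs <- replicate(300, {
    P <- matrix(rnorm(6 * 4), 6, 4)
    r <- crossval_accuracy_at_time(list(patterns = P, group = rep(1:3, 2),
                                        condition = sample(rep(c("a", "b"), 3))))
    r$correct / r$attempts
  })
  expect_equal(mean(accs), 0.5, tolerance = 0.05)
})

test_that("degenerate training sets fall back deterministically", {
  P <- matrix(1, 6, 4)  # identical patterns, opposite labels
  pats <- list(patterns = P, group = rep(1:3, 2),
               condition = rep(c("a", "b"), each = 3))
  res <- crossval_accuracy_at_time(pats)
  expect_equal(res$correct / res$attempts, 0.5)  # first-label rule: one of two right
})

test_that("smoothing is a truncated centered moving average", {
  expect_equal(smooth_timecourse(rep(0.7, 10), 5), rep(0.7, 10))
  imp <- c(rep(0, 5), 1, rep(0, 5))
  sm <- smooth_timecourse(imp, 5)
  expect_equal(sm[4:8], rep(0.2, 5))
  x <- runif(20)
  sm <- smooth_timecourse(x, 5)
  expect_equal(sm[10], mean(x[8:12]))   # interior: brute-force window mean
  expect_equal(sm[1], mean(x[1:3]))     # edge: truncated window
  expect_error(smooth_timecourse(x, 4), "odd")
  expect_error(smooth_timecourse(x[1:3], 5), "longer")
})

test_that("decoding a planted high-SNR effect is near-perfect after onset and reproducible", {
  cfg <- small_sim_config(effect_amplitude_uv = 30, noise_pink_sd = 1,
                          noise_alpha_power = 0, n_trials_per_condition = 12,
                          effect_onset_ms = 300, onset_sd_ms = 0, seed = 4)
  s <- generate_subject(cfg, 0)
  ep <- prep_for_decoding(s$cue)
  dc <- decoder_config(n_iterations = 5, seed = 8)
  tc <- decode_timecourse(ep, dc)
  expect_true(all(tc$accuracy >= 0 & tc$accuracy <= 1))
  expect_equal(unique(tc$n_attempts), 5 * 3 * 2)
  post <- tc$time > 600
  pre <- tc$time < 100
  expect_gt(mean(tc$accuracy[post]), 0.95)
  expect_lt(mean(tc$accuracy[pre]), 0.65)
  # fixed seed reproducibility to machine precision
  tc2 <- decode_timecourse(ep, dc)
  expect_identical(tc$accuracy, tc2$accuracy)
  # channel permutation invariance (same seed -> same partitions)
  perm <- sample(length(ep$channels))
  epp <- ep; epp$data <- ep$data[, perm, ]; epp$channels <- ep$channels[perm]
  tcp <- decode_timecourse(epp, dc)
  expect_equal(tcp$accuracy, tc$accuracy, tolerance = 1e-10)
  # common offset across channels removed by z-normalization
  epo <- ep; epo$data <- ep$data + 50
  tco <- decode_timecourse(epo, dc)
  expect_equal(tco$accuracy, tc$accuracy, tolerance = 1e-10)
})

test_that("a channel subset equal to all channels reproduces the full decode", {
  cfg <- small_sim_config(n_trials_per_condition = 9, seed = 14)
  s <- generate_subject(cfg, 0)
  ep <- subset_epochs(prep_for_decoding(s$cue), time_window = c(0, 400))
  dc <- decoder_config(n_iterations = 3, seed = 2)
  full <- decode_timecourse(ep, dc)
  sub <- channel_subset_decode(ep, labels = eeg_channels(ep), config = dc)
  expect_identical(sub$accuracy, full$accuracy)
  expect_error(channel_subset_decode(ep, labels = c("F7", "XX9"), config = dc),
               "missing channel")
})

test_that("activation maps recover a planted template under identity-like conditions", {
  # identity covariance: activation proportional to the weights
  set.seed(20)
  P <- rbind(matrix(rnorm(20, mean = 2), 2, 10),
             matrix(rnorm(20, mean = -2), 2, 10))
  m <- erpdecode:::fit_linear_svm(P, factor(rep(c("a", "b"), each = 2)), 1)
  act <- diag(10) %*% m$w
  expect_equal(as.vector(act), m$w)
  # template recovery at high SNR through the full pipeline
  cfg <- small_sim_config(effect_amplitude_uv = 25, noise_pink_sd = 1.5,
                          noise_alpha_power = 0, n_trials_per_condition = 12,
                          effect_onset_ms = 0, onset_sd_ms = 0,
                          link_strength = 0, seed = 33)
  s <- generate_subject(cfg, 0)
  ep <- subset_epochs(prep_for_decoding(s$cue), time_window = c(400, 800))
  tc <- decode_timecourse(ep, decoder_config(n_iterations = 5, seed = 1,
                                             return_maps = TRUE))
  tmpl <- erpdecode:::cue_template(montage_positions(eeg_channels(s$cue)))
  avg_map <- rowMeans(tc$maps)
  expect_gt(abs(cor(avg_map, tmpl)), 0.9)
})
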