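test_that("correlation time courses match the textbook Pearson computation", {
  # hand-checkable 5-subject fixture
  beh <- c(1, 2, 3, 4, 5)
  acc <- cbind(c(1, 2, 3, 4, 5),        # r = 1
               c(5, 4, 3, 2, 1),        # r = -1
               c(2, 1, 4, 3, 5))
  ct <- corr_timecourse(acc, beh)
  expect_equal(ct$r[1], 1)
  expect_equal(ct$r[2], -1)
  want <- cor.test(beh, acc[, 3])
  expect_equal(ct$r[3], unname(want$estimate))
  expect_equal(ct$p[3], want$p.value)
  # behavior = copy of accuracy at one point -> r = 1 there
  expect_equal(corr_timecourse(acc, acc[, 3])$r[3], 1)
  expect_error(corr_timecourse(acc[1:3, ], beh[1:3]), ">= 4")
  expect_error(corr_timecourse(acc, c(1, 2, NA, 4, 5)), "missing")
})

test_that("independent draws give near-zero r and uniform p", {
  set.seed(66)
  ps <- replicate(400, {
    corr_timecourse(matrix(rnorm(10), 10, 1), rnorm(10))$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
})

test_that("Liptak-Stouffer combination matches the normal-CDF oracle", {
  # frozen fixture computed from the probit transform ahead of the build:
  # p1 = p2 = 0.05, N = (30, 26) -> Z = 2.3246884061, p = 0.0100443138
  res <- liptak_stouffer(list(0.05, 0.05), ns = c(30, 26))
  expect_equal(res$z, 2.3246884061, tolerance = 1e-8)
  expect_equal(res$p, 0.0100443138, tolerance = 1e-7)
  # p = 0.5 in both datasets -> Z = 0 -> combined p = 0.5
  half <- liptak_stouffer(list(c(0.5, 0.5), c(0.5, 0.5)), ns = c(30, 26))
  expect_equal(half$z, c(0, 0))
  expect_equal(half$p, c(0.5, 0.5))
  # single dataset: identity
  p <- c(0.2, 0.04, 0.9)
  expect_equal(liptak_stouffer(list(p), ns = 26)$p, p, tolerance = 1e-12)
  # dataset order invariance with equal N
  ab <- liptak_stouffer(list(c(0.1), c(0.6)), ns = c(20, 20))
  ba <- liptak_stouffer(list(c(0.6), c(0.1)), ns = c(20, 20))
  expect_equal(ab$p, ba$p)
  # extreme p values are clipped with a warning
  expect_warning(ex <- liptak_stouffer(list(c(0, 1)), ns = 10), "clipped")
  expect_true(all(is.finite(ex$z)))
})

test_that("the identity shuffle reproduces the observed correlation statistics", {
  set.seed(10)
  acc <- matrix(rnorm(20 * 15), 20, 15)
  beh <- rnorm(20)
  perms <- matrix(1:20, 20, 1)
  p_perm <- erpdecode:::perm_corr_p(acc, beh, perms)
  obs <- erpdecode:::pearson_cols(beh, acc)
  expect_equal(as.vector(p_perm), obs$p, tolerance = 1e-10)
})

test_that("cluster permutation finds a planted coupling and respects its conventions", {
  set.seed(23)
  n <- 26; nt <- 40
  time <- seq(0, by = 20, length.out = nt)
  beh <- rnorm(n)
  acc <- matrix(rnorm(n * nt, sd = 0.05), n, nt) + 0.6
  planted <- 12:20
  acc[, planted] <- acc[, planted] + 0.08 * beh  # strong coupling
  res <- cluster_permutation(acc, beh, time, n_perm = 300, seed = 6)
  expect_gt(nrow(res$clusters), 0)
  top <- res$clusters[which.max(res$clusters$size), ]
  expect_lte(top$p, 0.05)
  # the detected cluster overlaps the planted window
  expect_lt(top$start_ms, time[max(planted)])
  expect_gt(top$end_ms, time[min(planted)])
  # cluster p values follow the >= (ties count) percentile convention
  k <- top$size
  expect_equal(top$p, mean(res$null_sizes >= k))
  expect_equal(top$p_less_than, all(res$null_sizes < k))
  expect_length(res$null_sizes, 300)
  # shared shuffle: permuting time points together preserves the null
  # structure -- structurally asserted: each iteration derives one p value
  # per time point from one subject permutation
  expect_equal(dim(res$clusters)[2], 9)
  expect_warning(cluster_permutation(acc, beh, time, n_perm = 50, seed = 1),
                 "100 permutations")
})

test_that("two-dataset permutation combines p values meta-analytically", {
  set.seed(31)
  n1 <- 14; n2 <- 12; nt <- 30
  time <- seq(0, by = 20, length.out = nt)
  b1 <- rnorm(n1); b2 <- rnorm(n2)
  a1 <- matrix(rnorm(n1 * nt, sd = 0.05), n1, nt)
  a2 <- matrix(rnorm(n2 * nt, sd = 0.05), n2, nt)
  win <- 10:16
  a1[, win] <- a1[, win] + 0.1 * b1
  a2[, win] <- a2[, win] + 0.1 * b2
  res <- cluster_permutation(list(a1, a2), list(b1, b2), time,
                             n_perm = 200, seed = 2)
  # observed per-point p equals the Liptak-Stouffer combination of the
  # two datasets' correlation p values
  p1 <- erpdecode:::pearson_cols(b1, a1)$p
  p2 <- erpdecode:::pearson_cols(b2, a2)$p
  expect_equal(res$observed_p, liptak_stouffer(list(p1, p2), c(n1, n2))$p,
               tolerance = 1e-12)
  expect_gt(nrow(res$clusters), 0)
  expect_error(cluster_permutation(list(a1, a2[, 1:10]), list(b1, b2),
                                   time, n_perm = 100), "identical time axis")
})

test_that("the univariate counterpart reduces to the single-channel analysis", {
  set.seed(41)
  n <- 16; nt <- 25
  time <- seq(0, by = 20, length.out = nt)
  beh <- rnorm(n)
  dw <- array(rnorm(n * 1 * nt, sd = 0.5), dim = c(n, 1, nt))
  dw[, 1, 8:14] <- dw[, 1, 8:14] + 0.8 * beh
  uni <- univariate_corr(dw, beh, time, channels = "Pz", n_perm = 200, seed = 3)
  single <- corr_timecourse(dw[, 1, ], beh)
  expect_equal(as.vector(uni$r), single$r, tolerance = 1e-12)
  expect_equal(as.vector(uni$p_raw), single$p, tolerance = 1e-12)
  # with one channel, BH across channels is the identity
  expect_equal(uni$p_fdr, uni$p_raw)
  expect_gt(nrow(uni$clusters$Pz), 0)
  # behavior equal to one channel/time value attains the minimum p there
  set.seed(13)
  dw2 <- array(rnorm(n * 3 * nt), dim = c(n, 3, nt))
  beh2 <- dw2[, 2, 10]
  uni2 <- univariate_corr(dw2, beh2, time, channels = c("a", "b", "c"),
                          n_perm = 50, seed = 4)
  expect_equal(which.min(uni2$p_raw), which(seq_len(3 * nt) ==
                                              (10 - 1) * 3 + 2))
})

test_that("behavior summaries compute RT statistics over correct response trials", {
  tr <- data.frame(rt = c(400, 500, 600, 700, NA, 300),
                   correct = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
                   attention = c("cued", "cued", "uncued", "uncued",
                                 "uncued", "cued"))
  bs <- behavior_summaries(tr)
  expect_equal(bs$mean_rt, mean(c(400, 500, 600, 700)))
  expect_equal(bs$median_rt, 550)
  expect_equal(bs$rt_difference, 650 - 450)
  expect_equal(bs$n_trials_used, 4)
  # valid mean 500 vs invalid 560 -> +60 difference
  tr2 <- data.frame(rt = c(500, 500, 560, 560), correct = TRUE,
                    attention = c("cued", "cued", "uncued", "uncued"))
  expect_equal(behavior_summaries(tr2)$rt_difference, 60)
  # brute-force agreement on random tables
  set.seed(77)
  tr3 <- data.frame(rt = rnorm(50, 500, 50),
                    correct = runif(50) > 0.1,
                    attention = sample(c("cued", "uncued"), 50, replace = TRUE))
  bs3 <- behavior_summaries(tr3)
  ok <- tr3$correct
  expect_equal(bs3$mean_rt, mean(tr3$rt[ok]))
  expect_equal(bs3$median_rt, median(tr3$rt[ok]))
  expect_error(behavior_summaries(data.frame(rt = NA_real_, correct = FALSE,
                                             attention = "cued")),
               "no correct")
})
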