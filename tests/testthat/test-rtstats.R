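test_that("quintile binning reproduces an explicit sort-and-average oracle", {
  # exactly 5 trials: one per bin
  obs <- make_obs(1, 30, bias = c(10, 8, 6, 4, 2), rt = c(0.1, 0.2, 0.3, 0.4, 0.5))
  q <- quintile_summary(obs)
  expect_equal(q$participant$mean_bias_deg, c(10, 8, 6, 4, 2))
  expect_equal(q$participant$mean_rt_s, c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(q$participant$n_trials, rep(1L, 5))

  # 10 noiseless trials with bias = 100 - 100 * rt; oracle = explicit sort
  set.seed(1)
  rt <- sample(seq(0.1, 1.0, by = 0.1))
  obs <- make_obs(1, 90, bias = 100 - 100 * rt, rt = rt)
  q <- quintile_summary(obs)
  srt <- sort(rt)
  oracle_rt <- colMeans(matrix(srt, nrow = 2))
  expect_equal(q$participant$mean_rt_s, oracle_rt)
  expect_equal(q$participant$mean_bias_deg, 100 - 100 * oracle_rt)

  # remainder spreads over the earliest bins: 12 trials -> 3,3,2,2,2
  obs <- make_obs(1, 60, bias = 0, rt = seq(0.1, 1.2, by = 0.1))
  q <- quintile_summary(obs)
  expect_equal(q$participant$n_trials, c(3L, 3L, 2L, 2L, 2L))

  # bins partition the valid trials
  expect_equal(sum(q$participant$n_trials), 12L)
})

test_that("small cells are omitted with a message and group SEM uses participants", {
  obs <- rbind(make_obs(1, 30, bias = 1:8, rt = (1:8) / 10),
               make_obs(2, 30, bias = 3 + (1:8), rt = (1:8) / 10),
               make_obs(3, 30, bias = 1:3, rt = (1:3) / 10))
  expect_message(q <- quintile_summary(obs), "omitting 1")
  expect_equal(sort(unique(q$participant$participant)), c(1, 2))
  expect_equal(q$group$n_participants, rep(2L, 5))
  # SEM = SD over participant means / sqrt(n); constant offset of 3 => sd 3/sqrt(2)...
  expect_equal(q$group$sem_deg, rep(stats::sd(c(0, 3)) / sqrt(2), 5))
})

test_that("two-stage slope is exact on noiseless linear data", {
  obs <- dplyr::bind_rows(lapply(1:4, function(p) {
    rt <- seq(0.1, 0.6, by = 0.05)
    make_obs(p, 60, bias = 50 - 100 * rt, rt = rt)
  }))
  s <- slope_fit(obs, 60)
  expect_equal(s$slope, -100)
  expect_equal(s$se, 0)
  expect_equal(s$p_value, 0)

  # commutativity with normalization on noiseless data
  sn <- slope_fit(normalize_bias(obs), 60)
  expect_equal(sn$slope, s$slope / 60, tolerance = 1e-9)
})

test_that("slopes are null-calibrated when bias is independent of RT", {
  set.seed(42)
  rejections <- 0L
  for (i in 1:20) {
    obs <- dplyr::bind_rows(lapply(1:8, function(p) {
      make_obs(p, 90, bias = rnorm(20, 10, 5), rt = runif(20, 0.1, 0.6))
    }))
    s <- slope_fit(obs, 90)
    if (s$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 4L)
})

test_that("mixed-model slope agrees with the two-stage estimate on balanced data", {
  set.seed(8)
  obs <- dplyr::bind_rows(lapply(1:10, function(p) {
    rt <- runif(40, 0.1, 0.6)
    make_obs(p, 90, bias = rnorm(1, 30, 5) - 80 * rt + rnorm(40, 0, 6),
             rt = rt)
  }))
  s1 <- slope_fit(obs, 90, method = "two_stage")
  s2 <- slope_fit(obs, 90, method = "pooled_mixed")
  expect_equal(sign(s1$slope), sign(s2$slope))
  expect_lt(abs(s1$slope - s2$slope), 2 * max(s1$se, s2$se))
  expect_gt(s2$df, 0)
})

test_that("bias normalization is the per-distance fraction of full bias", {
  obs <- make_obs(1, c(90, 30, 60, 0), bias = c(90, 3, 0, 5),
                  rt = c(0.2, 0.3, 0.4, 0.5))
  nb <- normalize_bias(obs)
  expect_equal(nrow(nb), 3) # frequent-target rows excluded
  expect_equal(nb$bias_deg, c(1, 0.1, 0))
  expect_equal(nb$bias_raw_deg, c(90, 3, 0))
})

test_that("distance contrasts match a hand-computed paired t-test", {
  set.seed(19)
  n <- 10
  means <- cbind(rnorm(n, 8, 6), rnorm(n, 20, 6), rnorm(n, 28, 6))
  obs <- dplyr::bind_rows(lapply(seq_len(n), function(p) {
    make_obs(p, rep(c(30, 60, 90), each = 4),
             bias = rep(means[p, ], each = 4), rt = 0.3)
  }))
  ct <- distance_contrasts(obs)
  expect_equal(ct$tests$mean, colMeans(means), tolerance = 1e-9)
  expect_true(all(diff(ct$tests$mean) > 0))

  # textbook paired t on the 30v60 contrast
  d <- means[, 2] - means[, 1]
  t_oracle <- mean(d) / (sd(d) / sqrt(n))
  row <- ct$contrasts[ct$contrasts$contrast == "30v60", ]
  expect_equal(row$t, t_oracle, tolerance = 1e-9)
  expect_equal(row$dz, mean(d) / sd(d), tolerance = 1e-9)
  expect_lt(row$p_bonf, 0.05)
  # Bonferroni definition
  expect_equal(ct$contrasts$p_bonf, pmin(1, 3 * ct$contrasts$p_raw))

  # all-zero biases: no test rejects
  obs0 <- dplyr::bind_rows(lapply(1:5, function(p) {
    make_obs(p, rep(c(30, 60, 90), each = 3), bias = 0, rt = 0.3)
  }))
  ct0 <- distance_contrasts(obs0)
  expect_true(all(ct0$tests$mean == 0))
})

test_that("reward comparison is null on identical groups and validates labels", {
  base <- dplyr::bind_rows(lapply(1:6, function(p) {
    rbind(make_obs(p, 0, bias = rnorm(10, 0, 3), rt = 0.3,
                   group = "reward", is_probe = FALSE),
          make_obs(p, rep(c(30, 60, 90), each = 5),
                   bias = rnorm(15, 3, 3), rt = 0.3, group = "reward"))
  }))
  set.seed(77)
  mirror <- base
  mirror$participant <- mirror$participant + 100
  mirror$group <- "no_reward"
  rw <- reward_compare(rbind(base, mirror))
  expect_equal(rw$accuracy$t, 0)
  expect_equal(rw$accuracy$d, 0)
  int_row <- rw$probe_model[grepl(":", rw$probe_model$term), ]
  expect_lt(int_row$F, 1e-6)

  expect_error(reward_compare(base), "reward")
})
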