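test_that("single-Gaussian fit is the closed-form MLE with a variance floor", {
  f <- fit_gmm(rep(5, 200), 1)
  expect_equal(f$means, 5)
  expect_equal(f$sds, 0.5) # sqrt of the 0.25 deg^2 floor
  expect_true(f$converged)

  set.seed(2)
  x <- rnorm(300, 2, 6)
  f <- fit_gmm(x, 1)
  expect_equal(f$means, mean(x))
  expect_equal(f$sds, sqrt(sum((x - mean(x))^2) / length(x)))
  expect_equal(f$loglik, sum(dnorm(x, f$means, f$sds, log = TRUE)))
})

test_that("two-component EM recovers well-separated clusters", {
  set.seed(7)
  lab <- rep(c(1, 2), each = 100)
  x <- c(rnorm(100, 0, 3), rnorm(100, 60, 3))
  f <- fit_gmm(x, 2, seed = 1)
  # oracle: per-cluster sample statistics with known labels
  expect_lt(abs(f$means[1] - mean(x[lab == 1])), 1)
  expect_lt(abs(f$means[2] - mean(x[lab == 2])), 1)
  expect_lt(abs(f$weights[1] - 0.5), 0.07)
  expect_lt(abs(f$sds[1] - sd(x[lab == 1])), 1)
  # nesting: richer model never fits worse
  f1 <- fit_gmm(x, 1)
  expect_gte(f$loglik, f1$loglik - 1e-6)
  expect_true(f$converged)
})

test_that("EM log-likelihood is nondecreasing across iterations", {
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(150, 0, 5) + sample(c(0, 40), 150, replace = TRUE,
                                   prob = c(0.7, 0.3))
    f <- fit_gmm(x, 2, n_restarts = 3, seed = i)
    expect_true(all(diff(f$loglik_trace) >= -1e-7))
  }
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(withr::local_package("mclust")) # Mclust needs attachment
  set.seed(5)
  x <- c(rnorm(150, 2, 4), rnorm(80, 45, 8))
  ours <- fit_gmm(x, 2, seed = 3)
  ref <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(ours$means), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.05)
  expect_equal(ours$loglik, ref$loglik, tolerance = 1e-3)
})

test_that("degenerate and undersized inputs are handled explicitly", {
  expect_error(fit_gmm(c(1, 2), 1), "3k")
  expect_error(fit_gmm(c(1, NA, 3, 4), 1), "finite")
  expect_warning(f <- fit_gmm(rep(3, 50), 2), "degenerate")
  expect_true(f$degenerate)
  expect_equal(f$weights, c(0.5, 0.5))
})

test_that("bimodality test rejects separated clusters and respects its p floor", {
  set.seed(3)
  x <- c(rnorm(100, 0, 3), rnorm(100, 60, 3))
  m <- modality_test(x, n_boot = 199, seed = 8)
  expect_lte(m$p_value, 0.05)
  expect_gte(m$p_value, 1 / 200)
  expect_gte(m$lrt_stat, -1e-6)
  expect_equal(length(m$boot_stats), 199)

  # unimodal data: statistic stays small-ish and p large (single draw)
  set.seed(4)
  m0 <- modality_test(rnorm(200, 0, 5), n_boot = 99, seed = 9)
  expect_gte(m0$lrt_stat, -1e-6)
  expect_gt(m0$p_value, 1 / 100)
})

test_that("peak estimate collapses correctly on constant data", {
  p <- peak_ci(rep(3, 50), n_boot = 200, seed = 1, k = 1)
  expect_equal(p$peak, 3)
  expect_equal(c(p$ci_low, p$ci_high), c(3, 3))
})

test_that("peak estimation is sign-equivariant", {
  set.seed(21)
  x <- rnorm(400, 3, 4)
  a <- peak_ci(x, n_boot = 1000, seed = 33, k = 1)
  b <- peak_ci(-x, n_boot = 1000, seed = 33, k = 1)
  expect_equal(b$peak, -a$peak, tolerance = 1e-12)
  expect_equal(b$ci_low, -a$ci_high, tolerance = 1e-12)
  expect_equal(b$ci_high, -a$ci_low, tolerance = 1e-12)

  set.seed(22)
  y <- c(rnorm(150, 3, 4), rnorm(100, 55, 6))
  a2 <- peak_ci(y, n_boot = 500, seed = 34, k = 2)
  b2 <- peak_ci(-y, n_boot = 500, seed = 34, k = 2)
  expect_equal(b2$peak, -a2$peak, tolerance = 0.05)
  expect_equal(b2$ci_low, -a2$ci_high, tolerance = 0.1)
  # nearest-to-zero rule: reported peak is the component closest to the probe
  expect_equal(a2$peak, a2$fit$means[which.min(abs(a2$fit$means))])
})

test_that("automatic component selection follows the modality decision", {
  set.seed(31)
  uni <- rnorm(300, 3, 4)
  bi <- c(rnorm(150, 2, 4), rnorm(150, 60, 5))
  p_uni <- peak_ci(uni, n_boot = 500, seed = 41, modality_n_boot = 99)
  p_bi <- peak_ci(bi, n_boot = 500, seed = 42, modality_n_boot = 99)
  expect_equal(p_uni$k, 1L)
  expect_equal(p_bi$k, 2L)
  expect_lt(abs(p_bi$peak - 2), 1.5)
})
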