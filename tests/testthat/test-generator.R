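test_that("clipped-rotation heading law honours its limiting contracts", {
  qp <- quiet_params()
  # preparation at the re-aiming onset: full default-plan bias
  set.seed(1)
  expect_equal(as.numeric(sample_heading(90, rt = qp$t0, qp)), 90,
               tolerance = 1e-6)
  # no bias at the frequent target
  expect_equal(as.numeric(sample_heading(0, rt = 0.5, qp)), 0,
               tolerance = 1e-6)
  # hand-evaluated clip: max(3, 60 - 300 * (0.5 - 0.1)) = 3
  expect_equal(as.numeric(sample_heading(60, rt = 0.5, qp)), 3,
               tolerance = 1e-6)
  expect_error(sample_heading(60, rt = -0.1, qp), "negative rt")
  expect_error(sample_heading(45, rt = 0.2, qp), "probe_distance")
})

test_that("bias is non-increasing in preparation time and clipped to [eps, d]", {
  qp <- quiet_params()
  for (d in c(30, 60, 90)) {
    b <- as.numeric(sample_heading(rep(d, 60), rt = seq(0, 0.6, length.out = 60), qp))
    expect_true(all(diff(b) <= 1e-6)) # slack for the tiny residual noise SD
    expect_true(all(b >= qp$eps_exec - 1e-6 & b <= d + 1e-6))
  }
  # property over random preparation times, noise-free, no lapses
  set.seed(99)
  for (i in 1:20) {
    d <- sample(c(30, 60, 90), 1)
    b <- as.numeric(sample_heading(rep(d, 50), rt = runif(50, 0, 1), qp))
    expect_true(all(b >= qp$eps_exec - 1e-6 & b <= d + 1e-6))
  }
})

test_that("generated reaction times follow the shifted log-normal law", {
  p <- default_params("exp1")
  ds <- generate_dataset("exp1", p, n_participants = 12, seed = 21,
                         trajectories = FALSE)
  rt <- ds$trials$rt_latent_s
  expect_gte(length(rt), 1e4)
  expect_true(min(rt) >= p$rt_shift)
  ks <- suppressWarnings(
    stats::ks.test(rt - p$rt_shift, "plnorm", p$rt_mu, p$rt_sigma))
  expect_gt(ks$p.value, 0.01)
})

test_that("delayed-response probes are essentially all fully re-aimed", {
  ds <- generate_dataset("exp2", n_participants = 2, seed = 3,
                         trajectories = FALSE)
  lt <- ds$latent[ds$latent$is_probe & ds$latent$phase == "test", ]
  expect_gt(mean(lt$regime == "re_aimed"), 0.95)
})

test_that("latent bias correlates negatively with RT on distant probes", {
  ds <- generate_dataset("exp1", n_participants = 4, seed = 11,
                         trajectories = FALSE)
  lt <- ds$latent[ds$latent$is_probe & ds$latent$phase == "test" &
                    ds$latent$probe_distance == 90 & !ds$latent$lapse, ]
  expect_lt(cor(lt$bias_exec_deg, lt$rt_latent_s), -0.3)
})

test_that("dataset generation is deterministic given the seed", {
  a <- generate_dataset("exp1", n_participants = 1, seed = 5)
  b <- generate_dataset("exp1", n_participants = 1, seed = 5)
  expect_identical(a$trials, b$trials)
  expect_identical(a$latent, b$latent)
  expect_identical(a$trajectories, b$trajectories)
})

test_that("datasets round-trip through the canonical CSV layout", {
  dir <- withr::local_tempdir()
  a <- generate_dataset("exp2", n_participants = 1, seed = 9,
                        trajectories = FALSE)
  write_dataset(a, dir)
  expect_true(all(file.exists(file.path(dir, c("trials.csv", "latent.csv",
                                               "params.json")))))
  b <- read_dataset(dir)
  expect_equal(b$design, "exp2")
  expect_equal(unclass(b$params), unclass(a$params))
  expect_equal(nrow(b$trials), nrow(a$trials))
  expect_equal(b$trials$rt_latent_s, a$trials$rt_latent_s)
})

test_that("trajectories hold before onset and ray out at the planned heading", {
  qp <- quiet_params()
  tr <- render_trajectory(45, rt = 0.3, move_time = 0.3, qp,
                          jitter = c(0, 0))
  sp <- abs(diff(sqrt(tr$x_cm^2 + tr$y_cm^2))) / diff(tr$t_s)
  expect_true(all(sp[tr$t_s[-1] < 0.3] < 3))
  post <- tr[tr$t_s > 0.3 & sqrt(tr$x_cm^2 + tr$y_cm^2) > 1e-9, ]
  expect_equal(atan2(post$y_cm, post$x_cm) * 180 / pi,
               rep(45, nrow(post)), tolerance = 1e-9)
  expect_gte(max(sqrt(tr$x_cm^2 + tr$y_cm^2)), 10 - 1e-9)
  expect_error(render_trajectory(45, rt = 0.3, move_time = 0, qp),
               "move_time")
})
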