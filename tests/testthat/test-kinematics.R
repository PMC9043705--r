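test_that("onset detection matches the analytic minimum-jerk oracle", {
  qp <- quiet_params()
  rt <- 0.25
  mt <- 0.30
  tr <- render_trajectory(30, rt, mt, qp, jitter = c(0, 0))
  onset <- detect_onset(tr$t_s, tr$x_cm, tr$y_cm)
  # oracle: first 5 ms grid time whose analytic speed exceeds 3 cm/s
  grid <- tr$t_s
  oracle <- grid[which(minjerk_speed(grid, rt, mt) > 3)[1]]
  expect_lte(abs(onset - oracle), 0.005 + 1e-9)

  # stationary trajectory never crosses the threshold
  n <- 50
  expect_true(is.na(detect_onset(seq(0, by = 0.005, length.out = n),
                                 rep(1, n), rep(2, n))))
})

test_that("onset recovery over random latent RTs stays within one sample of the oracle", {
  qp <- quiet_params()
  set.seed(4)
  for (i in 1:15) {
    rt <- runif(1, 0.1, 0.5)
    mt <- runif(1, 0.25, 0.40)
    tr <- render_trajectory(120, rt, mt, qp, jitter = c(0, 0))
    onset <- detect_onset(tr$t_s, tr$x_cm, tr$y_cm)
    oracle <- tr$t_s[which(minjerk_speed(tr$t_s, rt, mt) > 3)[1]]
    expect_lte(abs(onset - oracle), 0.005 + 1e-9)
  }
})

test_that("heading at 40 ms is exact on rays and matches the chord oracle on arcs", {
  qp <- quiet_params()
  tr <- render_trajectory(45, 0.2, 0.3, qp, jitter = c(0, 0))
  expect_equal(heading_at(tr$t_s, tr$x_cm, tr$y_cm, onset = 0.2), 45,
               tolerance = 1e-9)
  expect_equal(heading_at(tr$t_s, tr$x_cm, tr$y_cm, onset = 0.2, dt = 0.1),
               45, tolerance = 1e-9)

  # circular arc of known centre/radius: chord angle has a closed form
  omega_a <- 2 * pi # rad/s
  t <- seq(0, 0.5, by = 0.005)
  cx <- 1; cy <- -2; R <- 3
  x <- cx + R * cos(omega_a * t)
  y <- cy + R * sin(omega_a * t)
  onset <- 0.0525 # off the sample grid: exercises interpolation
  dt <- 0.04
  chord_oracle <- function(t1, t2) {
    # direction of P(t2) - P(t1) on the circle
    a1 <- omega_a * t1; a2 <- omega_a * t2
    atan2(sin(a2) - sin(a1), cos(a2) - cos(a1)) * 180 / pi
  }
  got <- heading_at(t, x, y, onset, dt)
  expect_equal(got, wrap_deg(chord_oracle(onset, onset + dt)),
               tolerance = 0.05)
  expect_error(heading_at(t, x, y, onset = 0.49, dt = 0.04), "too short")
})

test_that("validity screen applies the 70 ms and 400 ms criteria inclusively", {
  expect_equal(flag_validity(0.069, 0.3), "too_fast")
  expect_equal(flag_validity(0.3, 0.401), "too_slow")
  expect_equal(flag_validity(0.070, 0.400), "ok")
  expect_equal(flag_validity(NA, 0.3), "no_onset")
  expect_equal(flag_validity(0.2, NA), "too_slow")
  expect_equal(flag_validity(c(0.05, 0.2), c(0.3, 0.3)),
               c("too_fast", "ok"))
})

test_that("baseline table is the per-cell mean deviation and flags missing cells", {
  b <- tibble::tibble(participant = 1,
                      target_deg = rep(c(0, 30), each = 3),
                      heading_deg = c(0, 0, 0, 32, 28, 36))
  tab <- build_baseline(b)
  expect_equal(tab$baseline_deg[tab$target_deg == 0], 0)
  expect_equal(tab$baseline_deg[tab$target_deg == 30], 2)
  expect_error(build_baseline(b, targets = c(0, 30, 60)),
               "missing baseline cell.*60")
})

test_that("bias recoding fixes the toward-frequent sign convention", {
  # target counterclockwise of frequent: heading short of target is inward
  r <- recode_bias(80, 90, 60)
  expect_equal(r$probe_distance, 30)
  expect_equal(r$bias_deg, 10)
  # mirror case
  r <- recode_bias(40, 30, 60)
  expect_equal(r$probe_distance, 30)
  expect_equal(r$bias_deg, 10)
  # identity at the frequent target
  r <- recode_bias(150, 150, 150)
  expect_equal(r$probe_distance, 0)
  expect_equal(r$bias_deg, 0)
  # wrap-around location: from 330 the frequent target at 60 lies CCW
  r <- recode_bias(335, 330, 60, baseline = 0)
  expect_equal(r$probe_distance, 90)
  expect_equal(r$bias_deg, 5)
  expect_error(recode_bias(10, 45, 60), "session set")
})

test_that("zero-noise pipeline recovers latent biases and RTs", {
  qp <- quiet_params()
  ds <- generate_dataset("exp1", qp, n_participants = 1, seed = 13)
  obs <- process_dataset(ds)
  m <- merge(obs, ds$latent[, c("participant", "block", "trial",
                                "bias_exec_deg", "rt_latent_s")],
             by = c("participant", "block", "trial"))
  tst <- m[m$phase == "test" & m$valid, ]
  expect_gt(nrow(tst), 600)
  expect_lt(max(abs(tst$bias_deg - tst$bias_exec_deg)), 0.1)

  # RT: latent onset plus the threshold-crossing offset, to one sample
  mt <- ds$trials$move_time_s[match(
    paste(tst$participant, tst$block, tst$trial),
    paste(ds$trials$participant, ds$trials$block, ds$trials$trial))]
  oracle <- mapply(function(rt, mt_i) {
    tgrid <- seq(0, rt + mt_i + 0.01, by = 0.005)
    tgrid[which(minjerk_speed(tgrid, rt, mt_i) > 3)[1]]
  }, tst$rt_latent_s, mt)
  expect_lt(max(abs(tst$rt_s - oracle)), 0.005 + 1e-9)
})

test_that("biases are invariant to workspace rotation and mirror reflection", {
  ds <- generate_dataset("exp1", n_participants = 1, seed = 17)
  obs <- process_dataset(ds)

  rotate <- function(ds, phi) {
    a <- phi * pi / 180
    tr <- data.table::copy(ds$trajectories)
    x <- tr$x_cm * cos(a) - tr$y_cm * sin(a)
    y <- tr$x_cm * sin(a) + tr$y_cm * cos(a)
    tr[, `:=`(x_cm = x, y_cm = y)]
    ds$trajectories <- tr
    ds$trials$target_deg <- (ds$trials$target_deg + phi) %% 360
    ds$trials$target_nominal_deg <- (ds$trials$target_nominal_deg + phi) %% 360
    ds$trials$frequent_deg <- (ds$trials$frequent_deg + phi) %% 360
    ds
  }
  obs_rot <- process_dataset(rotate(ds, 17))
  expect_equal(obs_rot$bias_deg, obs$bias_deg, tolerance = 1e-6)
  expect_equal(obs_rot$probe_distance, obs$probe_distance)

  # reflect about the frequent-target axis: the built-in sign flip makes
  # recoded biases invariant
  reflect <- function(ds) {
    f <- ds$trials$frequent_deg[1] * pi / 180
    tr <- data.table::copy(ds$trajectories)
    # reflection about the line through origin at angle f
    x <- tr$x_cm * cos(2 * f) + tr$y_cm * sin(2 * f)
    y <- tr$x_cm * sin(2 * f) - tr$y_cm * cos(2 * f)
    tr[, `:=`(x_cm = x, y_cm = y)]
    ds$trajectories <- tr
    ds$trials$target_deg <- (2 * ds$trials$frequent_deg -
                               ds$trials$target_deg) %% 360
    ds$trials$target_nominal_deg <- (2 * ds$trials$frequent_deg -
                                       ds$trials$target_nominal_deg) %% 360
    ds
  }
  obs_ref <- process_dataset(reflect(ds))
  expect_equal(obs_ref$probe_distance, obs$probe_distance)
  # at the frequent target the toward-frequent sign is conventional, so the
  # invariance holds for probe distances > 0 and up to sign at 0
  d_pos <- obs$probe_distance > 0
  expect_equal(obs_ref$bias_deg[d_pos], obs$bias_deg[d_pos],
               tolerance = 1e-6)
  expect_equal(abs(obs_ref$bias_deg[!d_pos]), abs(obs$bias_deg[!d_pos]),
               tolerance = 1e-6)
})
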