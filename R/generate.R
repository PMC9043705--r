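#' Sample planned heading biases under the clipped-rotation model
#'
#' Draws the signed heading bias (in bias coordinates: probe target at 0,
#' positive toward the frequent target) for trials at absolute probe distance
#' `probe_distance` with reaction time `rt`. Preparation time is
#' `P = rt + params$delay`. For `d > 0` the deterministic core is
#' `max(d - omega * max(0, P - t0), eps_exec)`; at the frequent target
#' (`d = 0`) the core is 0. Gaussian execution noise (`sigma_motor`) is added,
#' and lapse trials are replaced by a Uniform(-d - 30, d + 30) draw.
#'
#' Uses the current R random number stream; seed via `set.seed()` or
#' `withr::with_seed()` in the caller.
#'
#' @param probe_distance vector of absolute probe distances, each in
#'   {0, 30, 60, 90} degrees.
#' @param rt vector of reaction times in seconds (>= 0), recycled against
#'   `probe_distance`.
#' @param params an [generative_params()] object.
#' @param lapse optional logical vector marking lapse trials; if `NULL`,
#'   lapses are drawn with probability `params$p_lapse`.
#' @return numeric vector of biases in degrees, with attribute `"planned"`
#'   (the noise-free core) and `"lapse"`.
#' @export
sample_heading <- function(probe_distance, rt, params, lapse = NULL) {
  stopifnot(inherits(params, "udl_params"))
  if (any(rt < 0)) stop("negative rt")
  if (!all(probe_distance %in% c(0, 30, 60, 90))) {
    stop("probe_distance must be in {0, 30, 60, 90}")
  }
  n <- max(length(probe_distance), length(rt))
  d <- rep_len(probe_distance, n)
  rt <- rep_len(rt, n)
  P <- rt + params$delay
  core <- ifelse(
    d > 0,
    pmax(d - params$omega * pmax(0, P - params$t0), params$eps_exec),
    0
  )
  b <- core + stats::rnorm(n, 0, params$sigma_motor)
  if (is.null(lapse)) lapse <- stats::runif(n) < params$p_lapse
  lapse <- rep_len(lapse, n)
  if (any(lapse)) {
    b[lapse] <- stats::runif(sum(lapse), -d[lapse] - 30, d[lapse] + 30)
  }
  attr(b, "planned") <- core
  attr(b, "lapse") <- lapse
  b
}

#' Planning regime implied by preparation time
#'
#' Classifies trials as `default` (re-aiming not yet begun, `P <= t0`),
#' `re_aimed` (rotation complete, only the execution shift remains) or
#' `intermediate`.
#'
#' @inheritParams sample_heading
#' @return character vector.
#' @export
regime_of <- function(probe_distance, rt, params) {
  P <- rt + params$delay
  thresh <- params$t0 + pmax(probe_distance - params$eps_exec, 0) / params$omega
  ifelse(P <= params$t0 & probe_distance > 0, "default",
         ifelse(P >= thresh, "re_aimed", "intermediate"))
}

minjerk_frac <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Render a single 200 Hz reach trajectory
#'
#' The hand holds a constant start offset until `rt`, then travels along a
#' straight ray at `heading_deg` with a minimum-jerk radial speed profile,
#' reaching the 10 cm target amplitude at `rt + move_time` and holding there.
#' Sample times are seconds from the trial's timebase zero (target onset for
#' the self-paced design, imperative for the delayed design).
#'
#' @param heading_deg screen-frame heading of the reach, degrees.
#' @param rt movement onset time in seconds (>= 0).
#' @param move_time movement duration in seconds (> 0).
#' @param params an [generative_params()] object (start jitter SD).
#' @param jitter optional length-2 start offset in cm; drawn from
#'   `N(0, params$jitter_sd)` when `NULL`.
#' @param hz sampling rate; fixed at 200 Hz in the canonical format.
#' @return tibble with columns `t_s`, `x_cm`, `y_cm`.
#' @export
render_trajectory <- function(heading_deg, rt, move_time, params,
                              jitter = NULL, hz = 200) {
  if (move_time <= 0) stop("move_time must be > 0")
  if (rt < 0) stop("rt must be >= 0")
  h <- 1 / hz
  if (is.null(jitter)) jitter <- stats::rnorm(2, 0, params$jitter_sd)
  t <- seq(0, by = h, length.out = ceiling((rt + move_time) / h) + 2L)
  r <- 10 * minjerk_frac((t - rt) / move_time)
  a <- heading_deg * pi / 180
  tibble::tibble(t_s = t,
                 x_cm = jitter[1] + r * cos(a),
                 y_cm = jitter[2] + r * sin(a))
}

# Vectorised batch renderer used by generate_dataset(); one row per sample.
render_trajectories <- function(trials, params, hz = 200) {
  h <- 1 / hz
  n_samp <- ceiling((trials$rt_latent_s + trials$move_time_s) / h) + 2L
  jit_x <- stats::rnorm(nrow(trials), 0, params$jitter_sd)
  jit_y <- stats::rnorm(nrow(trials), 0, params$jitter_sd)
  idx <- sequence(n_samp)
  row <- rep(seq_len(nrow(trials)), n_samp)
  t <- (idx - 1L) * h
  tau <- (t - trials$rt_latent_s[row]) / trials$move_time_s[row]
  r <- 10 * minjerk_frac(tau)
  a <- trials$heading_deg[row] * pi / 180
  data.table::data.table(
    participant = trials$participant[row],
    block = trials$block[row],
    trial = trials$trial[row],
    t_s = t,
    x_cm = jit_x[row] + r * cos(a),
    y_cm = jit_y[row] + r * sin(a)
  )
}

#' Generate a full synthetic dataset for one cohort
#'
#' Builds the trial schedule, draws latent reaction times from the shifted
#' log-normal law, realises heading biases under the clipped-rotation model,
#' and (optionally) renders 200 Hz trajectories. Baseline-phase reaches carry
#' no use-dependent bias, only execution noise plus a per
#' participant-by-location idiosyncratic bias that is also present in the test
#' phase (this is what baseline correction removes). Lapses occur in the test
#' phase; under a delayed design they are rendered as anticipatory responses
#' with RT below the 70 ms screen.
#'
#' @inheritParams make_schedule
#' @param params an [generative_params()] object; defaults to
#'   [default_params()] for the design.
#' @param trajectories logical; render 200 Hz trajectories (needed for the
#'   kinematics path) or stop at latent headings.
#' @return an object of class `udl_dataset`: a list with `design`, `params`,
#'   `seed`, `trials` (schedule plus latent RT, movement time, executed
#'   heading and regime), `latent` (truth table for recovery tests) and
#'   `trajectories` (data.table or `NULL`).
#' @export
generate_dataset <- function(design = c("exp1", "exp2"),
                             params = NULL,
                             n_participants = 10,
                             seed = 1L,
                             frequent_loc = NULL,
                             trajectories = TRUE) {
  design <- match.arg(design)
  if (is.null(params)) params <- default_params(design)
  stopifnot(inherits(params, "udl_params"))

  trials <- make_schedule(design, n_participants, frequent_loc, seed)
  withr::local_seed(as.integer(seed) + 1L)
  n <- nrow(trials)

  rt <- params$rt_shift + stats::rlnorm(n, params$rt_mu, params$rt_sigma)
  is_test <- trials$phase == "test"
  lapse <- stats::runif(n) < params$p_lapse & is_test
  if (params$delay > 0) {
    # anticipations initiate within ~30 ms of the imperative, so measured
    # onsets (latent + threshold-crossing offset) stay under the 70 ms screen
    rt[lapse] <- stats::runif(sum(lapse), 0, 0.03)
  }

  # per-trial jitter of the frequent-target location (supplementary design)
  trials$target_nominal_deg <- trials$target_deg
  if (params$freq_loc_sd > 0) {
    jit_rows <- which(is_test & !trials$is_probe)
    trials$target_deg[jit_rows] <- wrap_deg(
      trials$target_deg[jit_rows] +
        stats::rnorm(length(jit_rows), 0, params$freq_loc_sd)) %% 360
  }

  # idiosyncratic per participant x nominal-location bias
  idio <- lapply(unique(trials$participant), function(p) {
    tg <- session_targets(trials$frequent_deg[match(p, trials$participant)])
    tibble::tibble(participant = p, target_nominal_deg = tg,
                   idio_deg = stats::rnorm(7, 0, params$idio_sd))
  })
  idio <- dplyr::bind_rows(idio)
  trials <- dplyr::left_join(trials, idio,
                             by = c("participant", "target_nominal_deg"))

  bias <- numeric(n)
  planned <- numeric(n)
  b_test <- sample_heading(trials$probe_distance[is_test], rt[is_test],
                           params, lapse = lapse[is_test])
  bias[is_test] <- b_test
  planned[is_test] <- attr(b_test, "planned")
  bias[!is_test] <- stats::rnorm(sum(!is_test), 0, params$sigma_motor)

  sgn_gen <- ifelse(trials$rel_deg > 0, 1, -1)
  heading <- wrap_deg(trials$target_deg - sgn_gen * bias + trials$idio_deg)

  trials$rt_latent_s <- rt
  trials$move_time_s <- stats::runif(n, params$move_time_range[1],
                                     params$move_time_range[2])
  trials$heading_deg <- heading
  trials$regime <- ifelse(is_test,
                          regime_of(trials$probe_distance, rt, params),
                          "baseline")
  trials$lapse <- lapse

  latent <- tibble::tibble(
    participant = trials$participant, block = trials$block,
    trial = trials$trial, phase = trials$phase,
    probe_distance = trials$probe_distance, is_probe = trials$is_probe,
    rt_latent_s = rt, prep_s = rt + params$delay,
    bias_planned_deg = planned, bias_exec_deg = bias,
    heading_deg = heading, regime = trials$regime, lapse = lapse
  )

  traj <- NULL
  if (trajectories) traj <- render_trajectories(trials, params)

  structure(list(design = design, params = params, seed = as.integer(seed),
                 trials = trials, latent = latent, trajectories = traj),
            class = "udl_dataset")
}

#' @export
print.udl_dataset <- function(x, ...) {
  cat(sprintf("udl_dataset: design %s, %d participants, %d trials%s\n",
              x$design, length(unique(x$trials$participant)),
              nrow(x$trials),
              if (is.null(x$trajectories)) " (no trajectories)" else
                sprintf(", %d trajectory samples", nrow(x$trajectories))))
  invisible(x)
}

#' Write / read a dataset in the canonical CSV layout
#'
#' `trials.csv` holds one row per trial (schedule, latent RT, regime),
#' `trajectories.csv` one row per 200 Hz sample, `latent.csv` the generative
#' truth table, and `params.json` the generator parameters and design.
#'
#' @param dataset an `udl_dataset`.
#' @param dir output directory (created if needed).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` returns an
#'   `udl_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "udl_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(dataset$trials, file.path(dir, "trials.csv"))
  data.table::fwrite(dataset$latent, file.path(dir, "latent.csv"))
  if (!is.null(dataset$trajectories)) {
    data.table::fwrite(dataset$trajectories, file.path(dir, "trajectories.csv"))
  }
  meta <- c(unclass(dataset$params),
            list(design = dataset$design, seed = dataset$seed))
  jsonlite::write_json(meta, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "params.json"),
                              simplifyVector = TRUE)
  params <- do.call(generative_params,
                    meta[setdiff(names(meta), c("design", "seed"))])
  trials <- tibble::as_tibble(data.table::fread(file.path(dir, "trials.csv")))
  latent <- tibble::as_tibble(data.table::fread(file.path(dir, "latent.csv")))
  traj_path <- file.path(dir, "trajectories.csv")
  traj <- if (file.exists(traj_path)) data.table::fread(traj_path) else NULL
  structure(list(design = meta$design, params = params,
                 seed = as.integer(meta$seed), trials = trials,
                 latent = latent, trajectories = traj),
            class = "udl_dataset")
}
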