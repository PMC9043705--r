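#' Detect movement onset by a tangential speed threshold
#'
#' Speed is estimated by central differences on the sampling grid (one-sided
#' at the ends, no smoothing); onset is the first sample time at which speed
#' exceeds `v_thresh`. Returns `NA_real_` when the threshold is never crossed
#' (validity reason `no_onset`).
#'
#' @param t sample times in seconds (uniform grid, >= 2 samples).
#' @param x,y position in cm.
#' @param v_thresh speed threshold in cm/s; default 3.
#' @return onset time in seconds, or `NA_real_`.
#' @export
detect_onset <- function(t, x, y, v_thresh = 3) {
  n <- length(t)
  stopifnot(n >= 2, length(x) == n, length(y) == n)
  v <- trajectory_speed(t, x, y)
  hit <- which(v > v_thresh)
  if (length(hit) == 0L) return(NA_real_)
  t[hit[1L]]
}

trajectory_speed <- function(t, x, y) {
  n <- length(t)
  i0 <- c(1L, seq_len(n - 2L), n - 1L)
  i1 <- c(2L, seq_len(n - 2L) + 2L, n)
  sqrt((x[i1] - x[i0])^2 + (y[i1] - y[i0])^2) / (t[i1] - t[i0])
}

#' Heading angle a fixed interval after movement onset
#'
#' The screen-frame heading of the displacement between the position at
#' `onset` and at `onset + dt` (linear interpolation between samples). The
#' default 40 ms interval indexes the initial movement plan before online
#' corrections (about 2.4 cm of travel at typical speeds).
#'
#' @inheritParams detect_onset
#' @param onset movement onset time in seconds.
#' @param dt interval in seconds; default 0.040.
#' @return heading in degrees, wrapped to (-180, 180].
#' @export
heading_at <- function(t, x, y, onset, dt = 0.040) {
  if (onset + dt > max(t) || onset < min(t)) {
    stop("trajectory too short for heading at onset + dt")
  }
  px <- stats::approx(t, x, xout = c(onset, onset + dt))$y
  py <- stats::approx(t, y, xout = c(onset, onset + dt))$y
  wrap_deg(atan2(py[2] - py[1], px[2] - px[1]) * 180 / pi)
}

#' Validity screen for reaction and movement times
#'
#' `too_fast` marks anticipatory responses initiated within 70 ms of the
#' timebase zero; `too_slow` marks movement times over the 400 ms cap (or
#' reaches that never attain the target amplitude, `mt = NA`). Boundaries are
#' inclusive: rt = 0.070 and mt = 0.400 are `ok`.
#'
#' @param rt reaction time(s) in seconds (`NA` = onset never detected).
#' @param movement_time movement time(s) in seconds.
#' @return character vector of reason codes in
#'   {"ok", "too_fast", "too_slow", "no_onset"}.
#' @export
flag_validity <- function(rt, movement_time) {
  ifelse(is.na(rt), "no_onset",
         ifelse(rt < 0.070, "too_fast",
                ifelse(is.na(movement_time) | movement_time > 0.400,
                       "too_slow", "ok")))
}

#' Reduce raw trajectories to per-trial kinematic measures
#'
#' Batch version of [detect_onset()]/[heading_at()] over the canonical
#' trajectory table: per trial, movement onset (= RT), heading 40 ms after
#' onset, and movement time (onset to the first sample at >= 9.9 cm radial
#' extent, a tolerance under the 10 cm amplitude that accommodates start
#' jitter and slice-through endpoints).
#'
#' @param trajectories data frame with `participant`, `block`, `trial`,
#'   `t_s`, `x_cm`, `y_cm` (uniform 200 Hz within trial).
#' @param v_thresh onset speed threshold, cm/s.
#' @param heading_dt heading interval, seconds.
#' @param amp_thresh radial extent defining movement end, cm.
#' @return tibble with `participant`, `block`, `trial`, `rt_s`,
#'   `heading_deg`, `mt_s`.
#' @export
reduce_trajectories <- function(trajectories, v_thresh = 3,
                                heading_dt = 0.040, amp_thresh = 9.9) {
  dt <- data.table::as.data.table(trajectories)
  data.table::setorder(dt, participant, block, trial, t_s)
  dt[, idx := seq_len(.N), by = .(participant, block, trial)]
  dt[, `:=`(
    x_p = data.table::shift(x_cm, 1L), x_n = data.table::shift(x_cm, -1L),
    y_p = data.table::shift(y_cm, 1L), y_n = data.table::shift(y_cm, -1L),
    t_p = data.table::shift(t_s, 1L), t_n = data.table::shift(t_s, -1L)
  ), by = .(participant, block, trial)]
  # one-sided differences at the trial ends
  dt[is.na(x_p), `:=`(x_p = x_cm, y_p = y_cm, t_p = t_s)]
  dt[is.na(x_n), `:=`(x_n = x_cm, y_n = y_cm, t_n = t_s)]
  dt[, speed := sqrt((x_n - x_p)^2 + (y_n - y_p)^2) / pmax(t_n - t_p, 1e-12)]

  step <- dt[, stats::median(diff(t_s))]
  k <- as.integer(round(heading_dt / step))

  onset <- dt[speed > v_thresh,
              .(onset_idx = idx[1L], rt_s = t_s[1L]),
              by = .(participant, block, trial)]
  keys <- c("participant", "block", "trial")
  pos <- dt[, .(participant, block, trial, idx, t_s, x_cm, y_cm)]
  o1 <- pos[onset, on = c(keys, idx = "onset_idx")]
  o2 <- pos[onset[, .(participant, block, trial, idx2 = onset_idx + k)],
            on = c(keys, idx = "idx2")]
  onset[, heading_deg := wrap_deg(
    atan2(o2$y_cm - o1$y_cm, o2$x_cm - o1$x_cm) * 180 / pi)]

  reach_end <- dt[sqrt(x_cm^2 + y_cm^2) >= amp_thresh,
                  .(t_end = t_s[1L]), by = .(participant, block, trial)]
  out <- merge(
    unique(dt[, ..keys]),
    merge(onset[, c(keys, "rt_s", "heading_deg"), with = FALSE],
          reach_end, by = keys, all = TRUE),
    by = keys, all.x = TRUE
  )
  out[, mt_s := t_end - rt_s]
  tibble::as_tibble(out[, .(participant, block, trial, rt_s, heading_deg,
                            mt_s)])
}

#' Baseline bias table from the no-feedback baseline block
#'
#' Per participant and target location, the arithmetic mean of the wrapped
#' signed deviation `heading - target` in degrees. These idiosyncratic biases
#' are subtracted from every test-phase reach to the corresponding target.
#'
#' @param baseline data frame with `participant`, `target_deg`,
#'   `heading_deg` (valid no-feedback baseline reaches).
#' @param targets optional vector of target angles that must all be present
#'   for every participant; a missing cell is an error naming it.
#' @return tibble with `participant`, `target_deg`, `baseline_deg`.
#' @export
build_baseline <- function(baseline, targets = NULL) {
  stopifnot(all(c("participant", "target_deg", "heading_deg") %in%
                  names(baseline)))
  tab <- baseline |>
    dplyr::mutate(dev = wrap_deg(.data$heading_deg - .data$target_deg)) |>
    dplyr::group_by(.data$participant, .data$target_deg) |>
    dplyr::summarise(baseline_deg = mean(.data$dev), .groups = "drop")
  if (!all(is.finite(tab$baseline_deg))) stop("non-finite baseline mean")
  if (!is.null(targets)) {
    for (p in unique(baseline$participant)) {
      have <- tab$target_deg[tab$participant == p]
      miss <- setdiff(round(targets, 6), round(have, 6))
      if (length(miss) > 0) {
        stop(sprintf("missing baseline cell: participant %s, target %s deg",
                     p, paste(miss, collapse = ", ")))
      }
    }
  }
  tab
}

#' Recode a heading into probe distance and signed inward bias
#'
#' The frequent target is reset to 0 and the signed deviation from the
#' presented target is flipped so that positive values point toward the
#' frequent target, after subtracting the participant's baseline deviation
#' for that target. Probe distance is the absolute angular separation between
#' target and frequent target, collapsed onto {0, 30, 60, 90}.
#'
#' @param heading_deg observed heading(s), degrees, screen frame.
#' @param target_deg presented target angle(s), degrees.
#' @param frequent_deg frequent-target angle (scalar or vector).
#' @param baseline baseline deviation(s) in degrees to subtract (default 0).
#' @return tibble with `probe_distance` and `bias_deg`.
#' @export
recode_bias <- function(heading_deg, target_deg, frequent_deg, baseline = 0) {
  pd <- probe_distance_of(target_deg, frequent_deg)
  flip <- ifelse(pd$rel > 0, -1, 1)
  dev <- wrap_deg(heading_deg - target_deg) - baseline
  tibble::tibble(probe_distance = pd$distance, bias_deg = flip * dev)
}

#' Reduce a dataset to validated heading observations
#'
#' Runs the full measurement path: trajectory reduction (or, for datasets
#' generated without trajectories, the latent headings with latent RTs),
#' validity screening, baseline-table construction from the no-feedback
#' baseline block, and bias recoding of every trial. Baseline correction is
#' applied to test-phase reaches.
#'
#' @param dataset an `udl_dataset`, or a list with `trials` and
#'   `trajectories` in the canonical schemas.
#' @param v_thresh,heading_dt passed to [reduce_trajectories()].
#' @return tibble of observations: `participant`, `block`, `trial`, `phase`,
#'   `group`, `is_probe`, `target_deg`, `probe_distance`, `bias_deg`, `rt_s`,
#'   `mt_s`, `valid` (logical), `reason`.
#' @export
process_dataset <- function(dataset, v_thresh = 3, heading_dt = 0.040) {
  trials <- tibble::as_tibble(dataset$trials)
  if (!is.null(dataset$trajectories)) {
    meas <- reduce_trajectories(dataset$trajectories, v_thresh = v_thresh,
                                heading_dt = heading_dt)
  } else {
    meas <- tibble::tibble(participant = trials$participant,
                           block = trials$block, trial = trials$trial,
                           rt_s = trials$rt_latent_s,
                           heading_deg = trials$heading_deg,
                           mt_s = trials$move_time_s)
  }
  df <- dplyr::left_join(trials, meas,
                         by = c("participant", "block", "trial"),
                         suffix = c(".sched", ""))
  df$reason <- flag_validity(df$rt_s, df$mt_s)
  df$valid <- df$reason == "ok"

  base_rows <- df[df$phase == "baseline_nofeedback" & df$valid, ]
  btab <- build_baseline(
    base_rows[, c("participant", "target_deg", "heading_deg")],
    targets = NULL
  )
  nominal <- if ("target_nominal_deg" %in% names(df)) df$target_nominal_deg
             else df$target_deg
  df$baseline_deg <- btab$baseline_deg[match(
    paste(df$participant, round(nominal, 6)),
    paste(btab$participant, round(btab$target_deg, 6)))]
  if (anyNA(df$baseline_deg)) {
    miss <- df[is.na(df$baseline_deg), ][1, ]
    stop(sprintf("missing baseline cell: participant %s, target %s deg",
                 miss$participant, miss$target_deg))
  }
  use_base <- ifelse(df$phase == "test", df$baseline_deg, 0)

  rel <- wrap_deg(nominal - df$frequent_deg)
  flip <- ifelse(rel > 0, -1, 1)
  dev <- wrap_deg(df$heading_deg - df$target_deg) - use_base
  df$bias_deg <- flip * dev

  dplyr::select(tibble::as_tibble(df), "participant", "block", "trial",
                "phase", "group", "is_probe", "target_deg", "probe_distance",
                "bias_deg", "rt_s", "mt_s", "valid", "reason")
}

#' Simulate a cohort directly to heading observations
#'
#' Convenience wrapper: generates a dataset without trajectory rendering and
#' reduces it through the same baseline-correction and recoding path used for
#' measured trajectories. Observed RT equals latent RT on this path (the
#' onset-detection threshold-crossing offset is a near-constant shift shared
#' by all trials and is absorbed into the RT law).
#'
#' @inheritParams generate_dataset
#' @return tibble of observations (see [process_dataset()]), with the
#'   generating `udl_dataset` attached as attribute `"dataset"`.
#' @export
simulate_observations <- function(design = c("exp1", "exp2"), params = NULL,
                                  n_participants = 10, seed = 1L,
                                  frequent_loc = NULL) {
  ds <- generate_dataset(design, params, n_participants, seed, frequent_loc,
                         trajectories = FALSE)
  obs <- process_dataset(ds)
  attr(obs, "dataset") <- ds
  obs
}
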