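#' Reaction-time quintile summary of biases
#'
#' Per participant and probe distance, valid trials are sorted by RT and split
#' into `n_bins` bins (the first bin holding the fastest reaches; any
#' remainder is spread over the earliest bins), and the mean RT and mean bias
#' are computed per bin. Group curves are unweighted means over participants
#' with SEM = SD across participants / sqrt(n).
#'
#' @param observations observation tibble (see [process_dataset()]); only
#'   valid probe trials from the test phase are used.
#' @param n_bins number of RT bins; default 5 (quintiles).
#' @param min_trials cells with fewer valid trials are omitted (with a
#'   message); default `n_bins`.
#' @return list of class `udl_quintiles` with `participant` (per
#'   participant x distance x bin) and `group` (distance x bin with SEM).
#' @export
quintile_summary <- function(observations, n_bins = 5, min_trials = n_bins) {
  obs <- dplyr::filter(observations, .data$valid, .data$is_probe,
                       .data$phase == "test")
  small <- obs |>
    dplyr::count(.data$participant, .data$probe_distance) |>
    dplyr::filter(.data$n < min_trials)
  if (nrow(small) > 0) {
    message(sprintf("omitting %d participant x distance cell(s) with < %d trials",
                    nrow(small), min_trials))
    obs <- dplyr::anti_join(obs, small,
                            by = c("participant", "probe_distance"))
  }
  per <- obs |>
    dplyr::group_by(.data$participant, .data$probe_distance) |>
    dplyr::arrange(.data$rt_s, .by_group = TRUE) |>
    dplyr::mutate(quintile = rep(seq_len(n_bins),
                                 quintile_sizes(dplyr::n(), n_bins))) |>
    dplyr::group_by(.data$participant, .data$probe_distance,
                    .data$quintile) |>
    dplyr::summarise(mean_rt_s = mean(.data$rt_s),
                     mean_bias_deg = mean(.data$bias_deg),
                     n_trials = dplyr::n(), .groups = "drop")
  grp <- per |>
    dplyr::group_by(.data$probe_distance, .data$quintile) |>
    dplyr::summarise(mean_rt_s = mean(.data$mean_rt_s),
                     bias_deg = mean(.data$mean_bias_deg),
                     sem_deg = stats::sd(.data$mean_bias_deg) /
                       sqrt(dplyr::n()),
                     n_participants = dplyr::n(), .groups = "drop")
  structure(list(participant = per, group = grp), class = "udl_quintiles")
}

quintile_sizes <- function(n, n_bins) {
  sizes <- rep(n %/% n_bins, n_bins)
  rem <- n %% n_bins
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  sizes
}

#' Bias-versus-RT slope at one probe distance
#'
#' `two_stage` (default): ordinary least squares of bias on RT per
#' participant, then a one-sample t-test of the participant slopes against 0.
#' `pooled_mixed`: a participant-random-intercept mixed model on the pooled
#' trials (lmerTest; Satterthwaite degrees of freedom). Slopes are in degrees
#' per second.
#'
#' @param observations observation tibble; valid test-phase probe trials at
#'   `probe_distance` are used.
#' @param probe_distance the probe distance class (0, 30, 60 or 90).
#' @param method "two_stage" or "pooled_mixed".
#' @param min_trials participants with fewer trials at the distance are
#'   dropped from the two-stage fit (reported in `dropped`).
#' @return list of class `udl_slope`: `probe_distance`, `slope` (deg/s),
#'   `se`, `stat`, `df`, `p_value`, `method`, `per_participant` (two-stage)
#'   and `dropped`.
#' @export
slope_fit <- function(observations, probe_distance,
                      method = c("two_stage", "pooled_mixed"),
                      min_trials = 3) {
  method <- match.arg(method)
  d <- probe_distance
  obs <- dplyr::filter(observations, .data$valid, .data$is_probe,
                       .data$phase == "test", .data$probe_distance == d)
  if (length(unique(obs$participant)) < 2) {
    stop("need at least 2 participants")
  }
  if (method == "two_stage") {
    per <- obs |>
      dplyr::group_by(.data$participant) |>
      dplyr::summarise(
        n = dplyr::n(),
        slope = if (dplyr::n() >= min_trials &&
                    stats::sd(.data$rt_s) > 0)
          unname(stats::coef(stats::lm(bias_deg ~ rt_s,
                                       data = dplyr::pick(dplyr::everything())))[2])
        else NA_real_,
        .groups = "drop")
    dropped <- per$participant[is.na(per$slope)]
    sl <- per$slope[!is.na(per$slope)]
    if (stats::sd(sl) < 1e-12) {
      # degenerate case (e.g. noiseless data): slopes are identical
      out <- list(probe_distance = d, slope = mean(sl), se = 0,
                  stat = if (mean(sl) == 0) 0 else sign(mean(sl)) * Inf,
                  df = length(sl) - 1,
                  p_value = if (mean(sl) == 0) 1 else 0, method = method,
                  per_participant = per, dropped = dropped)
    } else {
      tt <- stats::t.test(sl)
      out <- list(probe_distance = d, slope = mean(sl),
                  se = stats::sd(sl) / sqrt(length(sl)),
                  stat = unname(tt$statistic), df = unname(tt$parameter),
                  p_value = tt$p.value, method = method,
                  per_participant = per, dropped = dropped)
    }
  } else {
    m <- lmerTest::lmer(bias_deg ~ rt_s + (1 | participant), data = obs)
    co <- stats::coef(summary(m))["rt_s", ]
    out <- list(probe_distance = d, slope = unname(co["Estimate"]),
                se = unname(co["Std. Error"]), stat = unname(co["t value"]),
                df = unname(co["df"]), p_value = unname(co["Pr(>|t|)"]),
                method = method, per_participant = NULL,
                dropped = character(0))
  }
  structure(out, class = "udl_slope")
}

#' @export
print.udl_slope <- function(x, ...) {
  cat(sprintf(
    "Bias-vs-RT slope at %d deg: %.1f +/- %.1f deg/s (t = %.2f, df = %.1f, p = %.3g; %s)\n",
    x$probe_distance, x$slope, x$se, x$stat, x$df, x$p_value, x$method))
  invisible(x)
}

#' Normalize biases within probe distance
#'
#' Divides each bias by its probe distance, giving a unitless fraction of the
#' maximal inward bias (1 = a full default-plan reach to the frequent
#' target). Frequent-target rows (`probe_distance == 0`) are excluded. The
#' raw bias is kept in `bias_raw_deg`.
#'
#' @param observations observation tibble.
#' @return the observations with `bias_deg` replaced by the normalized value.
#' @export
normalize_bias <- function(observations) {
  obs <- dplyr::filter(observations, .data$probe_distance > 0)
  obs$bias_raw_deg <- obs$bias_deg
  obs$bias_deg <- obs$bias_deg / obs$probe_distance
  obs
}

#' Per-distance bias means, tests against zero and paired contrasts
#'
#' Computes each participant's mean valid probe bias at 30, 60 and 90
#' degrees, one-sample t-tests of the participant means against zero per
#' distance, and paired contrasts (30 vs 60, 60 vs 90, 30 vs 90) with
#' Bonferroni correction for the three comparisons and within-subject
#' Cohen's d_z.
#'
#' @param observations observation tibble.
#' @return list of class `udl_contrasts` with `participant_means`, `tests`
#'   (per distance) and `contrasts`.
#' @export
distance_contrasts <- function(observations) {
  obs <- dplyr::filter(observations, .data$valid, .data$is_probe,
                       .data$phase == "test", .data$probe_distance > 0)
  pm <- obs |>
    dplyr::group_by(.data$participant, .data$probe_distance) |>
    dplyr::summarise(mean_bias = mean(.data$bias_deg), n = dplyr::n(),
                     .groups = "drop")
  if (length(unique(pm$participant)) < 2) stop("need at least 2 participants")

  tests <- pm |>
    dplyr::group_by(.data$probe_distance) |>
    dplyr::summarise(
      mean = mean(.data$mean_bias),
      sem = stats::sd(.data$mean_bias) / sqrt(dplyr::n()),
      t = stats::t.test(.data$mean_bias)$statistic,
      df = stats::t.test(.data$mean_bias)$parameter,
      p = stats::t.test(.data$mean_bias)$p.value,
      dz = mean(.data$mean_bias) / stats::sd(.data$mean_bias),
      .groups = "drop")

  wide <- tidyr::pivot_wider(pm[, c("participant", "probe_distance",
                                    "mean_bias")],
                             names_from = "probe_distance",
                             values_from = "mean_bias", names_prefix = "d")
  pairs <- list(c(30, 60), c(60, 90), c(30, 90))
  contrasts <- dplyr::bind_rows(lapply(pairs, function(pr) {
    a <- wide[[paste0("d", pr[1])]]
    b <- wide[[paste0("d", pr[2])]]
    keep <- stats::complete.cases(a, b)
    diff <- (b - a)[keep]
    tt <- stats::t.test(diff)
    tibble::tibble(contrast = sprintf("%dv%d", pr[1], pr[2]),
                   mean_diff = mean(diff),
                   sem = stats::sd(diff) / sqrt(length(diff)),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p_raw = tt$p.value,
                   p_bonf = min(1, 3 * tt$p.value),
                   dz = mean(diff) / stats::sd(diff))
  }))
  structure(list(participant_means = pm, tests = tests,
                 contrasts = contrasts),
            class = "udl_contrasts")
}

#' Reward-group comparison for the delayed-response design
#'
#' Manipulation check: per-participant mean absolute (baseline-corrected)
#' bias for reaches to the frequent target, compared between the reward and
#' no-reward groups with a two-sample t-test (pooled variance, Cohen's d).
#' Reward effects on probe biases: reward main effect and reward x
#' probe-distance interaction, fit on participant x distance mean biases with
#' a participant random intercept (lmerTest; Satterthwaite F-tests).
#' Aggregation to cell means avoids the pseudo-replication that the shared
#' per-location baseline correction would induce at trial level.
#'
#' @param observations observation tibble with a `group` column containing
#'   exactly the labels "reward" and "no_reward".
#' @return list of class `udl_reward`: `accuracy` (per-participant means and
#'   the group test) and `probe_model` (main-effect and interaction rows).
#' @export
reward_compare <- function(observations) {
  groups <- unique(observations$group)
  if (!setequal(groups, c("reward", "no_reward"))) {
    stop("groups must be exactly {reward, no_reward}; got: ",
         paste(groups, collapse = ", "))
  }
  freq <- dplyr::filter(observations, .data$valid, .data$phase == "test",
                        .data$probe_distance == 0)
  acc <- freq |>
    dplyr::group_by(.data$participant, .data$group) |>
    dplyr::summarise(mean_abs_bias = mean(abs(.data$bias_deg)),
                     .groups = "drop")
  a <- acc$mean_abs_bias[acc$group == "reward"]
  b <- acc$mean_abs_bias[acc$group == "no_reward"]
  tt <- stats::t.test(a, b, var.equal = TRUE)
  sp <- sqrt(((length(a) - 1) * stats::var(a) +
                (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
  acc_test <- list(mean_reward = mean(a), mean_no_reward = mean(b),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value, d = (mean(a) - mean(b)) / sp)

  cells <- observations |>
    dplyr::filter(.data$valid, .data$is_probe, .data$phase == "test",
                  .data$probe_distance > 0) |>
    dplyr::group_by(.data$participant, .data$group, .data$probe_distance) |>
    dplyr::summarise(bias = mean(.data$bias_deg), .groups = "drop") |>
    dplyr::mutate(group = factor(.data$group,
                                 levels = c("no_reward", "reward")),
                  distance = factor(.data$probe_distance))
  m <- lmerTest::lmer(bias ~ group * distance + (1 | participant),
                      data = cells)
  an <- stats::anova(m)
  probe_model <- tibble::tibble(
    term = rownames(an),
    F = an[["F value"]],
    df1 = an[["NumDF"]], df2 = an[["DenDF"]],
    p = an[["Pr(>F)"]]
  )
  structure(list(accuracy = c(list(per_participant = acc), acc_test),
                 probe_model = probe_model, model = m),
            class = "udl_reward")
}

#' @export
print.udl_reward <- function(x, ...) {
  cat(sprintf(
    "Frequent-target accuracy (mean |bias|): reward %.2f vs no-reward %.2f deg, t = %.2f, p = %.3g, d = %.2f\n",
    x$accuracy$mean_reward, x$accuracy$mean_no_reward, x$accuracy$t,
    x$accuracy$p, x$accuracy$d))
  pm <- x$probe_model
  for (i in seq_len(nrow(pm))) {
    cat(sprintf("  %-16s F(%d, %.1f) = %.2f, p = %.3g\n", pm$term[i],
                pm$df1[i], pm$df2[i], pm$F[i], pm$p[i]))
  }
  invisible(x)
}
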