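#' Configuration for an end-to-end pipeline run
#'
#' A validated container for everything a run needs; configurations
#' round-trip losslessly through YAML ([write_config()]/[read_config()]) and
#' are hashed into the run manifest so identical configurations provably
#' produce identical summaries.
#'
#' @param design "exp1" or "exp2".
#' @param n_participants cohort size to simulate (ignored when `data_dir`
#'   points at an existing canonical dataset).
#' @param seed master integer seed; all stage seeds derive from it.
#' @param params generator parameter overrides (named list) applied to
#'   [default_params()] for the design.
#' @param frequent_loc optional fixed frequent-target location.
#' @param data_dir optional directory with an existing canonical dataset to
#'   analyze instead of simulating.
#' @param use_trajectories render and reduce 200 Hz trajectories (the full
#'   measurement path) rather than analyzing latent headings directly.
#' @param n_boot_modality bootstrap replicates for bimodality tests.
#' @param n_boot_peak bootstrap resamples for peak CIs.
#' @param k_mode "auto" (modality-test decision) or a fixed 1 or 2.
#' @param slope_method "two_stage" or "pooled_mixed".
#' @param n_quintiles RT bins for the quintile analysis.
#' @param out_dir output directory for tables, summary and manifest.
#' @param make_figures write PNG figures (heading histograms, quintile
#'   curves).
#' @return list of class `udl_config`.
#' @export
run_config <- function(design = c("exp1", "exp2"), n_participants = 10,
                       seed = 1L, params = list(), frequent_loc = NULL,
                       data_dir = NULL, use_trajectories = TRUE,
                       n_boot_modality = 199, n_boot_peak = 2000,
                       k_mode = "auto", slope_method = "two_stage",
                       n_quintiles = 5, out_dir = tempfile("udl_run_"),
                       make_figures = FALSE) {
  design <- match.arg(design)
  stopifnot(is.numeric(seed), length(seed) == 1,
            k_mode %in% c("auto", "1", "2", 1, 2),
            slope_method %in% c("two_stage", "pooled_mixed"))
  structure(list(design = design, n_participants = n_participants,
                 seed = as.integer(seed), params = params,
                 frequent_loc = frequent_loc, data_dir = data_dir,
                 use_trajectories = isTRUE(use_trajectories),
                 n_boot_modality = n_boot_modality,
                 n_boot_peak = n_boot_peak, k_mode = k_mode,
                 slope_method = slope_method, n_quintiles = n_quintiles,
                 out_dir = out_dir, make_figures = isTRUE(make_figures)),
            class = "udl_config")
}

#' @rdname run_config
#' @param config an `udl_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

config_hash <- function(config) {
  key <- unclass(config)
  key$out_dir <- NULL
  key$make_figures <- NULL
  rlang::hash(key)
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> kinematics -> distributional analysis -> RT
#' statistics -> report. Writes the canonical CSVs, per-stage result tables
#' (`observations.csv`, `mixture_results.csv`, `slopes.csv`,
#' `quintiles.csv`, `contrasts.csv`, and `reward.csv` for two-group data),
#' a machine-readable `summary.json` and a `manifest.json` (config hash,
#' seed, package and R versions). Runs are deterministic given the
#' configuration: identical configs yield byte-identical summaries.
#'
#' @param config an [run_config()] object.
#' @return the summary list, invisibly, with attribute `"paths"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "udl_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  if (!is.null(config$data_dir)) {
    ds <- read_dataset(config$data_dir)
  } else {
    params <- do.call(default_params,
                      c(list(design = config$design), config$params))
    ds <- generate_dataset(config$design, params, config$n_participants,
                           seed = seed, frequent_loc = config$frequent_loc,
                           trajectories = config$use_trajectories)
  }
  obs <- process_dataset(ds)
  data.table::fwrite(obs, file.path(config$out_dir, "observations.csv"))
  excl <- table(obs$reason[obs$phase == "test"])
  message("pipeline: ", nrow(obs), " trials reduced; test-phase exclusions: ",
          paste(sprintf("%s=%d", names(excl), excl), collapse = ", "))

  probe <- dplyr::filter(obs, .data$valid, .data$is_probe,
                         .data$phase == "test")
  distances <- sort(unique(probe$probe_distance))
  forced_k <- if (config$k_mode == "auto") NULL else as.integer(config$k_mode)

  mix_rows <- list()
  for (i in seq_along(distances)) {
    d <- distances[i]
    x <- probe$bias_deg[probe$probe_distance == d]
    mod <- modality_test(x, n_boot = config$n_boot_modality,
                         seed = seed + 1000L + i)
    k_sel <- if (!is.null(forced_k)) forced_k else
      if (mod$p_value < 0.05) 2L else 1L
    pk <- peak_ci(x, n_boot = config$n_boot_peak, seed = seed + 2000L + i,
                  k = k_sel)
    f <- pk$fit
    mix_rows[[i]] <- tibble::tibble(
      probe_distance = d, n = length(x), k_selected = k_sel,
      lrt = mod$lrt_stat, p_bimodal = mod$p_value,
      mean1 = f$means[1], mean2 = if (f$k == 2) f$means[2] else NA_real_,
      sd1 = f$sds[1], sd2 = if (f$k == 2) f$sds[2] else NA_real_,
      weight1 = f$weights[1],
      weight2 = if (f$k == 2) f$weights[2] else NA_real_,
      peak = pk$peak, ci_low = pk$ci_low, ci_high = pk$ci_high)
  }
  mixture <- dplyr::bind_rows(mix_rows)
  data.table::fwrite(mixture, file.path(config$out_dir, "mixture_results.csv"))

  slopes <- dplyr::bind_rows(lapply(distances, function(d) {
    s <- slope_fit(obs, d, method = config$slope_method)
    tibble::tibble(probe_distance = d, slope = s$slope, se = s$se,
                   stat = s$stat, df = s$df, p = s$p_value,
                   method = s$method)
  }))
  data.table::fwrite(slopes, file.path(config$out_dir, "slopes.csv"))

  qt <- quintile_summary(obs, n_bins = config$n_quintiles)
  data.table::fwrite(qt$group, file.path(config$out_dir, "quintiles.csv"))

  ct <- distance_contrasts(obs)
  data.table::fwrite(ct$contrasts, file.path(config$out_dir, "contrasts.csv"))

  reward <- NULL
  if (setequal(unique(obs$group), c("reward", "no_reward"))) {
    rw <- reward_compare(obs)
    reward <- list(
      accuracy = rw$accuracy[c("mean_reward", "mean_no_reward", "t", "df",
                               "p", "d")],
      probe_model = rw$probe_model)
    data.table::fwrite(rw$probe_model, file.path(config$out_dir, "reward.csv"))
  }

  if (config$make_figures) {
    ggplot2::ggsave(file.path(config$out_dir, "heading_distributions.png"),
                    plot_heading_distribution(obs), width = 8, height = 6,
                    dpi = 120)
    ggplot2::ggsave(file.path(config$out_dir, "quintile_curves.png"),
                    plot_quintiles(qt), width = 6, height = 4, dpi = 120)
  }

  summary <- list(
    design = ds$design,
    n_participants = length(unique(ds$trials$participant)),
    n_trials = nrow(ds$trials),
    exclusions = as.list(excl),
    mixture = mixture,
    slopes = slopes,
    quintiles = qt$group,
    contrasts = ct$contrasts,
    distance_tests = ct$tests,
    reward = reward
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, dataframe = "rows")
  manifest <- list(config_hash = config_hash(config), seed = seed,
                   package_version = as.character(utils::packageVersion("udlreach")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  attr(summary, "paths") <- file.path(
    config$out_dir, c("summary.json", "manifest.json"))
  invisible(summary)
}

#' Validate a canonical dataset
#'
#' Schema, unit, sampling-rate and referential-integrity checks over the
#' canonical trial/trajectory pair. Returns a (possibly empty) violation
#' table rather than erroring, so it can be used as a pre-flight report.
#'
#' @param x an `udl_dataset`, a list with `trials`/`trajectories`, or a
#'   directory containing the canonical CSVs.
#' @param hz expected sampling rate; default 200.
#' @return tibble with columns `check`, `participant`, `block`, `trial`,
#'   `message`; zero rows means the dataset is clean.
#' @export
validate_dataset <- function(x, hz = 200) {
  if (is.character(x)) x <- read_dataset(x)
  trials <- tibble::as_tibble(x$trials)
  traj <- x$trajectories
  v <- list()
  add <- function(check, p = NA, b = NA, tr = NA, msg) {
    tibble::tibble(check = check, participant = p, block = b, trial = tr,
                   message = msg)
  }

  need <- c("participant", "block", "trial", "phase", "target_deg",
            "is_probe", "feedback", "group")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0) {
    v <- c(v, list(add("schema", msg = paste("trials.csv missing columns:",
                                             paste(miss, collapse = ", ")))))
  }
  if (is.null(traj)) {
    out <- dplyr::bind_rows(v)
    return(if (nrow(out) == 0) empty_violations() else out)
  }
  dtj <- data.table::as.data.table(traj)
  need_t <- c("participant", "block", "trial", "t_s", "x_cm", "y_cm")
  miss <- setdiff(need_t, names(dtj))
  if (length(miss) > 0) {
    return(add("schema",
               msg = paste("trajectories.csv missing columns:",
                           paste(miss, collapse = ", "))))
  }

  h <- 1 / hz
  rate <- dtj[, .(bad = max(abs(diff(t_s)) - h) > 1e-9),
              by = .(participant, block, trial)][bad == TRUE]
  if (nrow(rate) > 0) {
    v <- c(v, list(add("sampling_rate", rate$participant, rate$block,
                       rate$trial,
                       sprintf("sampling interval differs from %g s", h))))
  }
  ext <- dtj[, .(rmax = max(sqrt(x_cm^2 + y_cm^2))),
             by = .(participant, block, trial)][rmax < 9.5]
  if (nrow(ext) > 0) {
    v <- c(v, list(add("radial_extent", ext$participant, ext$block,
                       ext$trial, "radial extent never reaches 9.5 cm")))
  }

  tkey <- unique(dtj[, .(participant, block, trial)])
  skey <- unique(data.table::as.data.table(
    trials)[, .(participant, block, trial)])
  orphan <- tkey[!skey, on = c("participant", "block", "trial")]
  if (nrow(orphan) > 0) {
    v <- c(v, list(add("referential_integrity", orphan$participant,
                       orphan$block, orphan$trial,
                       "trajectory without a matching trial")))
  }
  lone <- skey[!tkey, on = c("participant", "block", "trial")]
  if (nrow(lone) > 0) {
    v <- c(v, list(add("referential_integrity", lone$participant,
                       lone$block, lone$trial,
                       "trial without a matching trajectory")))
  }
  out <- dplyr::bind_rows(v)
  if (nrow(out) == 0) empty_violations() else out
}

empty_violations <- function() {
  tibble::tibble(check = character(), participant = integer(),
                 block = integer(), trial = integer(), message = character())
}
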