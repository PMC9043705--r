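#!/usr/bin/env Rscript
# Reaction-time dependence of the biases: per-distance bias-vs-RT slopes
# (two-stage and mixed-model), RT quintile curves, and probe-distance
# contrasts. The self-paced cohort should show steep negative slopes that
# grow with probe distance; the delayed cohort, slopes near zero and bias
# means flat across distance.

suppressMessages(library(udlreach))

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

for (design in c("exp1", "exp2")) {
  path <- file.path("results/data", design, "observations.csv")
  if (!file.exists(path)) stop("run analysis/02_kinematics.R first")
  obs <- tibble::as_tibble(data.table::fread(path))

  slopes <- dplyr::bind_rows(lapply(c(0, 30, 60, 90), function(d) {
    s2 <- slope_fit(obs, d, method = "two_stage")
    sm <- slope_fit(obs, d, method = "pooled_mixed")
    message(sprintf(
      "%s d=%2d: slope %.1f +/- %.1f deg/s (two-stage, p=%.3g); %.1f deg/s (mixed)",
      design, d, s2$slope, s2$se, s2$p_value, sm$slope))
    tibble::tibble(design = design, probe_distance = d,
                   slope_two_stage = s2$slope, se_two_stage = s2$se,
                   p_two_stage = s2$p_value, slope_mixed = sm$slope,
                   se_mixed = sm$se, p_mixed = sm$p_value)
  }))
  data.table::fwrite(slopes, sprintf("results/tables/slopes_%s.csv", design))

  qt <- quintile_summary(obs)
  data.table::fwrite(qt$group,
                     sprintf("results/tables/quintiles_%s.csv", design))

  ct <- distance_contrasts(obs)
  print(ct$tests)
  print(ct$contrasts)
  data.table::fwrite(ct$contrasts,
                     sprintf("results/tables/contrasts_%s.csv", design))

  if (capabilities("png")) {
    dir.create("results/figures", showWarnings = FALSE)
    ggplot2::ggsave(sprintf("results/figures/quintiles_%s.png", design),
                    plot_quintiles(qt), width = 6, height = 4, dpi = 120)
  }
}
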