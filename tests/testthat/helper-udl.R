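# Shared fixtures built in code.

# Noise-free generator parameters (tiny positive SDs where zero is not
# allowed) for exact-recovery checks.
quiet_params <- function(design = "exp1", ...) {
  default_params(design, sigma_motor = 1e-9, idio_sd = 0, jitter_sd = 0,
                 p_lapse = 0, ...)
}

valid_probes <- function(obs, d = NULL) {
  out <- obs[obs$valid & obs$is_probe & obs$phase == "test", ]
  if (!is.null(out) && !is.null(d)) out <- out[out$probe_distance %in% d, ]
  out
}

# Minimal hand-built observation table for the RT-statistics module.
make_obs <- function(participant, probe_distance, bias, rt,
                     group = "exp1", phase = "test", is_probe = TRUE) {
  n <- max(length(participant), length(probe_distance), length(bias),
           length(rt))
  tibble::tibble(
    participant = rep_len(participant, n),
    block = 3L, trial = seq_len(n), phase = rep_len(phase, n),
    group = rep_len(group, n), is_probe = rep_len(is_probe, n),
    target_deg = 90, probe_distance = rep_len(probe_distance, n),
    bias_deg = rep_len(bias, n), rt_s = rep_len(rt, n), mt_s = 0.3,
    valid = TRUE, reason = "ok")
}

# Analytic minimum-jerk radial speed (cm/s) for a 10 cm reach of duration mt
# starting at rt: the independent oracle for onset detection.
minjerk_speed <- function(t, rt, mt) {
  tau <- (t - rt) / mt
  ifelse(tau <= 0 | tau >= 1, 0, 10 * (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / mt)
}
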