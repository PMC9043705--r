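#' Parameters of the two-process reach generator
#'
#' The generator realises a clipped-rotation account of use-dependent biases:
#' every reach starts from a default plan aimed at the frequent target and is
#' re-aimed toward the actual target at a constant angular rate once planning
#' begins, while execution carries a small stable shift toward the practiced
#' direction. For a probe at absolute distance `d` degrees from the frequent
#' target and preparation time `P` (reaction time plus any imposed
#' target-to-imperative delay), the planned bias toward the frequent target is
#'
#' \deqn{b = \max(d - \omega \max(0, P - t_0),\; \epsilon_{exec})}
#'
#' to which zero-mean Gaussian execution noise is added. Short preparation
#' reproduces the full default-plan bias (`b = d`), long preparation leaves
#' only the execution shift (`b = eps_exec`), and intermediate preparation
#' yields the broad band of intermediate headings seen in self-paced reaching.
#'
#' @param eps_exec stable execution shift toward the frequent target, degrees
#'   (>= 0). Default 3.
#' @param omega re-aiming rate from the default plan toward the actual target,
#'   degrees/second (> 0). Default 300.
#' @param t0 re-aiming onset latency after target presentation, seconds.
#'   Default 0.1.
#' @param sigma_motor execution noise SD, degrees (> 0). Default 4.
#' @param rt_mu,rt_sigma log-scale mean and SD of the log-normal reaction-time
#'   law. Defaults log(0.18) and 0.8 give a median self-paced RT of about
#'   0.25 s with both a fast-guess tail and a slow tail.
#' @param rt_shift minimum RT offset in seconds (>= 0); reaction times are
#'   `rt_shift + LogNormal(rt_mu, rt_sigma)`. Default 0.07, the anticipation
#'   floor used by the validity screen.
#' @param delay target-to-imperative interval in seconds: 0 for the self-paced
#'   design, 0.5 for the delayed-response design.
#' @param freq_loc_sd SD in degrees of per-trial jitter of the frequent-target
#'   location on non-probe trials (0, 7.5 or 15 in the supplementary design).
#'   Default 0.
#' @param move_time_range two-element range (seconds) of the uniform
#'   movement-time draw. Default c(0.25, 0.40).
#' @param p_lapse probability of a misdirected lapse reach, in [0, 0.05).
#'   Default 0.01. Under `delay > 0` lapses are rendered as anticipatory
#'   responses (RT below the 70 ms screen) rather than slow misdirected
#'   reaches, matching the canonical error mode of delayed-response tasks.
#' @param idio_sd SD in degrees of the per participant-by-location
#'   idiosyncratic bias that baseline correction is designed to remove.
#'   Default 2.
#' @param jitter_sd SD in cm of the constant start-position offset held before
#'   movement onset. Default 0.02.
#'
#' @return an object of class `udl_params` (a validated named list).
#' @seealso [default_params()], [generate_dataset()], [sample_heading()]
#' @export
generative_params <- function(eps_exec = 3.0,
                              omega = 300,
                              t0 = 0.1,
                              sigma_motor = 4,
                              rt_mu = log(0.18),
                              rt_sigma = 0.8,
                              rt_shift = 0.07,
                              delay = 0.0,
                              freq_loc_sd = 0,
                              move_time_range = c(0.25, 0.40),
                              p_lapse = 0.01,
                              idio_sd = 2,
                              jitter_sd = 0.02) {
  p <- list(eps_exec = eps_exec, omega = omega, t0 = t0,
            sigma_motor = sigma_motor, rt_mu = rt_mu, rt_sigma = rt_sigma,
            rt_shift = rt_shift, delay = delay, freq_loc_sd = freq_loc_sd,
            move_time_range = as.numeric(move_time_range), p_lapse = p_lapse,
            idio_sd = idio_sd, jitter_sd = jitter_sd)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || anyNA(p[[nm]])) {
      stop("parameter '", nm, "' must be numeric and non-missing")
    }
  }
  stopifnot(
    "eps_exec must be >= 0" = eps_exec >= 0,
    "omega must be > 0" = omega > 0,
    "t0 must be >= 0" = t0 >= 0,
    "sigma_motor must be > 0" = sigma_motor > 0,
    "rt_shift must be >= 0" = rt_shift >= 0,
    "delay must be >= 0" = delay >= 0,
    "freq_loc_sd must be >= 0" = freq_loc_sd >= 0,
    "move_time_range must be an increasing positive pair" =
      length(move_time_range) == 2 && move_time_range[1] > 0 &&
      move_time_range[2] >= move_time_range[1],
    "p_lapse must be in [0, 0.05)" = p_lapse >= 0 && p_lapse < 0.05,
    "idio_sd must be >= 0" = idio_sd >= 0,
    "jitter_sd must be >= 0" = jitter_sd >= 0
  )
  structure(p, class = "udl_params")
}

#' Default generator parameters for a study design
#'
#' @param design "exp1" (self-paced, no delay) or "exp2" (delayed response,
#'   0.5 s target-to-imperative interval).
#' @param ... overrides passed to [generative_params()].
#' @return an `udl_params` object.
#' @export
default_params <- function(design = c("exp1", "exp2"), ...) {
  design <- match.arg(design)
  dots <- list(...)
  if (is.null(dots$delay)) dots$delay <- if (design == "exp2") 0.5 else 0.0
  do.call(generative_params, dots)
}

#' @export
print.udl_params <- function(x, ...) {
  cat("Two-process reach generator parameters\n")
  cat(sprintf("  execution shift eps_exec : %.2f deg\n", x$eps_exec))
  cat(sprintf("  re-aiming rate omega     : %.1f deg/s (onset t0 = %.3f s)\n",
              x$omega, x$t0))
  cat(sprintf("  motor noise sigma        : %.2f deg\n", x$sigma_motor))
  cat(sprintf("  RT law                   : %.3f + LogNormal(%.3f, %.3f) s\n",
              x$rt_shift, x$rt_mu, x$rt_sigma))
  cat(sprintf("  delay                    : %.3f s\n", x$delay))
  cat(sprintf("  lapse probability        : %.3f\n", x$p_lapse))
  invisible(x)
}
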