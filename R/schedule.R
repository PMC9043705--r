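#' Build a trial schedule for one of the two study designs
#'
#' `exp1` (self-paced): per participant, two baseline blocks (10 reaches to
#' each of the seven session targets; the first with online cursor feedback,
#' the second with none) followed by eight test blocks of 90 trials. Each test
#' block opens with 10 reaches to the frequent target, then 80 trials of which
#' 66 are frequent-target reaches with feedback and 14 are no-feedback probes,
#' two at each of the seven locations. The 80 post-initial trials are divided
#' into 14 contiguous near-equal slots (ten of six trials, four of five, order
#' shuffled) with exactly one probe per slot, so probes are spread nearly
#' uniformly through the block.
#'
#' `exp2` (delayed response): the same two baseline blocks followed by six
#' test blocks of 134 trials: 113 frequent-target reaches (reward-eligible for
#' the reward group) and 21 no-feedback probes, three per location, one per
#' contiguous slot. Participants are split half/half into `reward` and
#' `no_reward` groups.
#'
#' The frequent-target location alternates between 60 and 150 degrees across
#' participants unless `frequent_loc` is supplied.
#'
#' @param design "exp1" or "exp2".
#' @param n_participants number of participants (>= 1).
#' @param frequent_loc optional scalar frequent-target angle applied to all
#'   participants; default alternates 60/150.
#' @param seed integer seed; the schedule is deterministic given the seed.
#' @return a tibble with one row per trial: `participant`, `block`, `trial`
#'   (within session), `block_trial`, `phase` (baseline_feedback /
#'   baseline_nofeedback / test), `slot` (probe slot index, NA outside test
#'   phase), `target_deg`, `frequent_deg`, `probe_distance`, `rel_deg`,
#'   `is_probe`, `feedback` (online_cursor / none / reward_binary), `group`.
#' @export
make_schedule <- function(design = c("exp1", "exp2"), n_participants,
                          frequent_loc = NULL, seed = 1L) {
  design <- match.arg(design)
  if (!is.numeric(n_participants) || n_participants < 1) {
    stop("n_participants must be >= 1")
  }
  n_participants <- as.integer(n_participants)
  if (!is.null(frequent_loc)) stopifnot(length(frequent_loc) == 1L)

  withr::local_seed(as.integer(seed))

  blocks_per_design <- if (design == "exp1") 8L else 6L
  probes_per_loc <- if (design == "exp1") 2L else 3L
  n_initial <- if (design == "exp1") 10L else 0L
  n_block <- if (design == "exp1") 90L else 134L

  out <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    freq <- if (!is.null(frequent_loc)) frequent_loc else
      if (p %% 2L == 1L) 60 else 150
    targets <- session_targets(freq)
    group <- if (design == "exp1") "exp1" else
      if (p <= ceiling(n_participants / 2)) "reward" else "no_reward"

    baseline <- function(block, phase, fb) {
      tgt <- sample(rep(targets, each = 10L))
      tibble::tibble(block = block, block_trial = seq_along(tgt),
                     phase = phase, slot = NA_integer_, target_deg = tgt,
                     is_probe = FALSE, feedback = fb)
    }

    test_block <- function(block) {
      n_main <- n_block - n_initial
      n_slots <- probes_per_loc * 7L
      sizes <- rep(n_main %/% n_slots, n_slots)
      rem <- n_main %% n_slots
      if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
      sizes <- sample(sizes)
      probe_targets <- sample(rep(targets, probes_per_loc))
      slot_id <- rep(seq_len(n_slots), sizes)
      is_probe <- logical(n_main)
      tgt <- rep(freq, n_main)
      pos <- cumsum(c(0L, sizes[-n_slots])) + vapply(sizes, function(s)
        sample.int(s, 1L), integer(1))
      is_probe[pos] <- TRUE
      tgt[pos] <- probe_targets
      freq_fb <- if (design == "exp1") "online_cursor" else
        if (group == "reward") "reward_binary" else "none"
      fb <- ifelse(is_probe, "none", freq_fb)
      tibble::tibble(
        block = block,
        block_trial = seq_len(n_block),
        phase = "test",
        slot = c(rep(NA_integer_, n_initial), slot_id),
        target_deg = c(rep(freq, n_initial), tgt),
        is_probe = c(rep(FALSE, n_initial), is_probe),
        feedback = c(rep(freq_fb, n_initial), fb)
      )
    }

    tb <- dplyr::bind_rows(
      baseline(1L, "baseline_feedback", "online_cursor"),
      baseline(2L, "baseline_nofeedback", "none"),
      dplyr::bind_rows(lapply(seq_len(blocks_per_design) + 2L, test_block))
    )
    pd <- probe_distance_of(tb$target_deg, freq)
    tb$participant <- p
    tb$frequent_deg <- freq
    tb$group <- group
    tb$probe_distance <- pd$distance
    tb$rel_deg <- pd$rel
    out[[p]] <- tb
  }
  sched <- dplyr::bind_rows(out)
  sched$trial <- stats::ave(seq_len(nrow(sched)), sched$participant,
                            FUN = seq_along)
  dplyr::select(sched, "participant", "block", "trial", "block_trial",
                "phase", "slot", "target_deg", "frequent_deg", "rel_deg",
                "probe_distance", "is_probe", "feedback", "group")
}
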