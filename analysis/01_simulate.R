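#!/usr/bin/env Rscript
# Simulate the two study cohorts with the two-process generator and write
# them in the canonical CSV layout under results/data/.
#
# Cohort 1 ("self-paced"): 10 participants, no target-imperative delay,
# 86.8%/2.2% target schedule, online feedback on frequent-target reaches.
# Cohort 2 ("delayed"): 16 + 16 participants (reward / no-reward groups),
# 500 ms target-to-imperative delay.

suppressMessages(library(udlreach))

seed <- 20260927L %% 100000L
out <- "results/data"

message("generating self-paced cohort (10 participants) ...")
ds1 <- generate_dataset("exp1", n_participants = 10, seed = seed)
write_dataset(ds1, file.path(out, "exp1"))

message("generating delayed-response cohort (32 participants) ...")
ds2 <- generate_dataset("exp2", n_participants = 32, seed = seed + 1L)
write_dataset(ds2, file.path(out, "exp2"))

for (ds in list(ds1, ds2)) {
  v <- validate_dataset(ds)
  stopifnot(nrow(v) == 0)
  lt <- ds$latent[ds$latent$phase == "test" & ds$latent$is_probe, ]
  message(sprintf(
    "%s: %d trials, %d probe trials; planning regimes: %s",
    ds$design, nrow(ds$trials), nrow(lt),
    paste(sprintf("%s %.0f%%", names(table(lt$regime)),
                  100 * prop.table(table(lt$regime))), collapse = ", ")))
}
message("done; canonical datasets under ", out)
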