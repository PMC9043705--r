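# udlreach

Decomposing use-dependent biases in centre-out reaching into a
**planning** component and an **execution** component.

## The problem

When one reach direction is practiced far more often than others (a
"frequent" target shown on ~87% of trials, six rare probe targets on ~2%
each), reaches to the probes are biased toward the practiced direction.
Two distinct mechanisms produce this bias:

* **Planning bias** — a default motor plan aimed at the frequent target
  that is re-aimed toward the actual target as preparation proceeds.
  Signatures: *bimodal* heading-angle distributions (peaks near both the
  probe and the frequent target), a broad band of intermediate headings,
  and a steeply negative dependence of bias on reaction time (RT).
* **Execution bias** — a small (~3°), stable shift of fully planned
  reaches toward the practiced direction. Signature: the peak of the
  heading distribution nearest the probe target sits a few degrees toward
  the frequent target, independent of RT, probe distance and reward.

A delayed-response design (500 ms between target and imperative) removes
the planning component, isolating the execution component.

`udlreach` implements, for researchers in motor learning and
psychophysics:

* a **two-process generative simulator** (schedules, latent headings, 200
  Hz stylus trajectories) with the clipped-rotation law
  `b = max(d − ω·max(0, P − t0), ε_exec) + noise`, where `d` is probe
  distance and `P` preparation time;
* **kinematics**: movement-onset detection (3 cm/s velocity threshold),
  heading 40 ms after onset, anticipation (<70 ms) / slow-movement
  (>400 ms) screening, baseline correction and toward-frequent bias
  recoding;
* the **distributional core**: 1- vs 2-component Gaussian mixtures by EM,
  a parametric-bootstrap likelihood-ratio test of bimodality, and
  percentile-bootstrap confidence intervals (10 000 resamples) for the
  peak nearest the probe — the execution-bias estimate;
* **RT statistics**: RT-quintile bias curves, per-distance bias-vs-RT
  slopes (two-stage OLS or mixed model), probe-distance contrasts with
  Bonferroni correction, and reward-group comparisons;
* a deterministic **pipeline** (`run_pipeline()`) plus an adapter stub
  (`read_dryad_deposit()`) for the published tablet-reaching deposit
  (Dryad DOI 10.6078/D1MX4P).

## Worked example

```r
library(udlreach)

# Delayed-response cohort, 16 participants: execution bias only
obs <- simulate_observations("exp2", n_participants = 16, seed = 8)
x60 <- subset(obs, valid & is_probe & phase == "test" & probe_distance == 60)
peak_ci(x60$bias_deg, n_boot = 10000, seed = 9, modality_n_boot = 199)
#> Peak near probe: 3.51 deg, 95% bootstrap CI [3.16, 3.86] (k = 1, n = 570)

# Self-paced cohort, 10 participants: planning bias dominates
obs1 <- simulate_observations("exp1", n_participants = 10, seed = 8)
slope_fit(obs1, 90)
#> Bias-vs-RT slope at 90 deg: -117.2 +/- 24.5 deg/s (t = -4.78, df = 9.0, p = 0.001; two_stage)
x90 <- subset(obs1, valid & is_probe & phase == "test" & probe_distance == 90)
modality_test(x90$bias_deg, n_boot = 999, seed = 10)
#> Bimodality LRT: stat 41.85, parametric bootstrap p = 0.001 (n_boot = 999)
```

Read: in the delayed cohort the heading distribution at the 60° probe is
unimodal (`k = 1`) but its peak is displaced **+3.5°** toward the frequent
target, with a 95% CI excluding 0 — the execution bias (the generating
value is 3°). In the self-paced cohort the 90° probe distribution is
bimodal (p = 0.001, the bootstrap floor) and bias falls by ~117°/s of
reaction time — the planning bias.

## Analysis workflow

Numbered drivers under `analysis/` run the full study-scale analysis and
write tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # two synthetic cohorts, canonical CSVs
Rscript analysis/02_kinematics.R   # trajectories -> validated observations
Rscript analysis/03_distributions.R# mixtures, bimodality tests, peak CIs
Rscript analysis/04_bias_rt.R      # slopes, quintiles, contrasts
Rscript analysis/05_reward.R       # reward comparison
```

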