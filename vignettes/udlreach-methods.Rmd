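---
title: "Decomposing use-dependent reaching biases: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing use-dependent reaching biases: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Repeating a movement biases later movements toward the practiced one
(use-dependent learning). In centre-out reaching with one *frequent* target
and six rarely probed targets, this bias has two dissociable sources:

* a **planning bias** — a default motor plan aimed at the frequent target
  that must be overridden when a probe target appears; its footprint is a
  broad, often bimodal distribution of initial heading angles and a steep
  negative dependence of the bias on reaction time (RT); and
* an **execution bias** — a small (~3°), temporally stable shift of
  well-planned reaches toward the practiced direction, read out as the
  displacement of the heading-distribution peak nearest the probe target,
  insensitive to RT, probe distance and reward.

`udlreach` implements the full measurement and inference chain for this
decomposition and a generative simulator that reproduces its statistical
structure, so every stage is testable without external data.

## The two-process generator

Angles are in degrees, screen frame, counterclockwise positive; biases are
in *bias coordinates* (probe target at 0, positive toward the frequent
target). For a probe at absolute distance $d \in \{0, 30, 60, 90\}$ and
preparation time $P$ (RT plus the imposed target-to-imperative delay, 0 s
for the self-paced design and 0.5 s for the delayed one), the planned bias
is a clipped rotation from the default plan toward the actual target:

$$ b(P) \;=\; \max\!\big(d - \omega\,\max(0, P - t_0),\; \epsilon_{exec}\big)
   \;+\; \mathcal N(0, \sigma_{motor}^2), \qquad d > 0 $$

with $b = \mathcal N(0, \sigma_{motor}^2)$ at the frequent target. Three
regimes follow: *default* ($P \le t_0$, full bias $d$), *intermediate*
(linear descent at $\omega$ deg/s), and *re-aimed* (only the execution
shift $\epsilon_{exec}$ remains). This is the smallest model that produces
all three empirical signatures — bimodal heading distributions, a broad band
of intermediate angles, and a negative bias–RT slope — from four
interpretable parameters, which is what makes parameter *recovery* a
meaningful test of the pipeline.

Defaults (units, value, why):

| parameter | default | meaning |
|---|---|---|
| `eps_exec` | 3.0° | execution shift; matches the ~3° peak displacements seen empirically |
| `omega` | 300 °/s | re-aiming rate; puts full re-aiming at ~0.4 s preparation for the farthest probe |
| `t0` | 0.1 s | re-aiming onset latency |
| `sigma_motor` | 4° | execution noise SD, typical of early-heading measures |
| `rt_shift`, `rt_mu`, `rt_sigma` | 0.07 s, log(0.18), 0.8 | RT = shift + log-normal; median ≈ 0.25 s |
| `delay` | 0 / 0.5 s | target-to-imperative interval per design |
| `move_time_range` | 0.25–0.40 s | uniform movement-time draw, under the 400 ms cap |
| `p_lapse` | 0.01 | misdirected lapse reaches |
| `idio_sd` | 2° | per participant × location idiosyncratic bias |
| `jitter_sd` | 0.02 cm | start-position offset held before onset |

Design choices that were genuinely open, and how they were settled:

* **RT law.** No RT distribution is available numerically, so
  `rt_mu`/`rt_sigma` are chosen for qualitative realism only: a broad
  log-normal whose fast-guess tail falls below the re-aiming onset (giving
  the default-plan cluster) and whose slow tail passes full re-aiming. They
  were fixed once, from the geometry of the clipped-rotation model, and are
  not fit to data.
* **Delayed preparation.** Preparation time is modelled as $P = RT + 0.5$ s:
  the entire delay is usable for planning, which is precisely the
  manipulation's intent. Consequently essentially every delayed-design trial
  is in the re-aimed regime.
* **Lapses.** In the self-paced design a lapse is a misdirected reach drawn
  uniformly over the target sector. In the delayed design the canonical
  error mode is *anticipation* — moving on target onset instead of the
  imperative — so lapse trials are rendered with onsets within 30 ms of the
  imperative; after the onset detector's threshold-crossing offset they
  still fall under the 70 ms screen and are removed by the validity flag,
  as they would be in practice.
  Lapses are restricted to the test phase; baseline familiarisation blocks
  are modelled as unhurried.
* **Idiosyncratic bias.** Without `idio_sd`, baseline correction would be a
  no-op on synthetic data; with it, the correction removes a real per
  participant × location offset, exactly as intended for real reaches.
* **Schedule slots.** Fourteen probes cannot be spaced exactly one per
  seven trials among 80 post-initial reaches, so probes are placed one per
  contiguous near-equal slot (ten slots of six trials, four of five, order
  shuffled), preserving the counts exactly and the spacing nearly.
* **Session geometry.** The seven-target set is frequent + {0, ±30, ±60,
  ±90}°, wrapped; for a frequent target at 60° this is the canonical
  0–150/330° display set, and it keeps probe distances well defined for the
  150° counterbalance.

What the generator does *not* emulate: online feedback corrections and
curved interception paths, reward-driven RT changes, trial-order learning
dynamics (the execution shift is stationary within a session), and heavy
non-Gaussian heading noise. A pipeline that passes on these synthetic
cohorts is therefore validated for its *statistical machinery*; claims
about real reaches still require the deposited data via
`read_dryad_deposit()`.

## Kinematics

Reaches are reduced exactly as the measurement chain prescribes:

* **Onset / RT**: first sample whose tangential speed exceeds 3 cm/s.
  Speed is a central difference on the 200 Hz grid, no smoothing: the
  synthetic data are noise-controlled, and the estimator is isolated in one
  function (`trajectory_speed`) for robustness work on real data.
* **Heading**: direction of the displacement from onset to onset + 40 ms
  (linear interpolation off-grid), indexing the initial plan before online
  corrections.
* **Validity**: `too_fast` strictly below 70 ms, `too_slow` strictly above
  400 ms (boundaries inclusive as `ok`); invalid trials are excluded from
  all downstream analyses and logged with reason codes.
* **Baseline correction**: per participant × target mean deviation in the
  no-feedback baseline block, subtracted from every test-phase reach.
* **Recoding**: deviations are wrapped to (−180°, 180°] and treated
  linearly thereafter; the sign is flipped so positive biases point toward
  the frequent target, and signed distances collapse to |30|, |60|, |90|
  after the flip (the analyses average across sides).
* **Movement end** is the first sample at ≥ 9.9 cm radial extent — a small
  tolerance under the 10 cm amplitude that accommodates start-position
  jitter.

Two invariances are enforced by test: rotating the whole workspace leaves
every bias unchanged, and reflecting it about the frequent-target axis
leaves biases unchanged too (the sign flip is built into the recoding).

## Distributional core

Heading-bias distributions per probe distance (pooled across participants,
matching the group histograms) are fit with one- and two-component Gaussian
mixtures by EM: below/above-median split plus jittered-quantile restarts
(10 by default), unequal variances floored at 0.25 deg², relative
log-likelihood tolerance 1e-8, iteration cap 300. The EM log-likelihood is
asserted non-decreasing per fit, and the fits are cross-checked against an
independent mixture implementation in the test suite.

**Bimodality** is decided by a parametric-bootstrap likelihood-ratio test:
simulate from the fitted single Gaussian, refit both models, and use the
add-one rule $p = (1 + \#\{T^* \ge T\})/(B+1)$. The observed and bootstrap
fits use identical EM settings (3 restarts inside the test) — using a more
thorough search on the observed statistic than on the null replicates would
make the test anticonservative. $B$ defaults to 999, and 199 inside
bootstrap-heavy loops; its only externally fixed counterpart is the peak
CI's 10 000.

**The execution-bias readout** is the mean of the component nearest 0, with
a nonparametric percentile bootstrap CI over trial resamples (BCa is not
used because nothing more specific than a "bootstrapped CI" is specified;
percentile is the simplest choice consistent with that). When the component
count is not forced, it follows the bimodality decision at α = 0.05.
Degenerate inputs (constant data with k = 2) return a flagged,
variance-floored fit rather than failing.

## RT statistics

* **Quintiles**: per participant × distance, RTs sorted ascending into five
  bins, remainder spread over the earliest (fastest) bins; group curves are
  unweighted participant means with SEM = SD/√n.
* **Slopes**: the default `two_stage` method (per-participant OLS, then a
  one-sample t-test on slopes) is fully self-contained; `pooled_mixed`
  delegates to lmerTest (participant random intercept, Satterthwaite df)
  and is labelled as such in outputs. Units are deg/s throughout — the
  scale on which the empirical slopes are tens of deg/s.
* **Contrasts**: per-distance one-sample tests and the three paired
  contrasts with Bonferroni ×3 and within-subject Cohen's d_z.
* **Reward**: the manipulation check compares per-participant mean |bias|
  at the frequent target between groups (pooled-variance t, Cohen's d).
  The reward main effect and reward × distance interaction are fit on
  participant × distance cell means with a participant random intercept:
  baseline correction induces a shared offset within each participant ×
  location cell, and trial-level mixed models with only a participant
  intercept are anticonservative under that correlation — aggregation
  restores calibration (verified by simulation in the acceptance tests).
  The ±5.7° reward criterion belongs to the generator's feedback rules,
  not to the analysis.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen once: the self-paced
cohort at its study size (10 participants; ~320 probes per distance
class), the delayed cohort at 16 + 16 (~1150 probes per distance);
bimodality rates over 20 seeded runs with B = 199; test calibration over
200 null simulations (B = 99) and CI coverage over 100 runs; reward
calibration and power over 100 seeded cohorts. Seeds are explicit
arguments everywhere; there is no hidden global RNG state, and identical
configurations produce byte-identical pipeline summaries.

One behaviour worth knowing: the parametric-bootstrap LRT is sensitive to
outliers, so in self-paced cohorts the ~1% lapse reaches can make it
reject unimodality even at the frequent target (distance 0), where the
underlying law is a single Gaussian. The substantive dissociation the
package tests concerns the probe distances, where the planning mechanism
itself — not contamination — carries the bimodality.

Known limitations: mixtures with more than two components and circular
(wrapped) mixtures are out of scope, as are dip-type modality tests; the
linear treatment of angular deviations is safe for the ±120° range the
task produces but would not generalise to full-circle designs; and the
execution shift is modelled as constant across probe distance, which is an
idealisation of the observed saturation.
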