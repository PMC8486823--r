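---
title: "From wearable event streams to phenotype classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From wearable event streams to phenotype classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearpipe)
```

`wearpipe` implements a desk-scale analysis chain for longitudinal consumer
wearable data: de-identification of event-timestamped streams, minute-level
harmonization, daily domain-knowledge feature extraction via heart-rate
stratification, user-level aggregation, repeated cross-validated elastic-net
classification, and a 2-D embedding of the day-level feature space. This
vignette explains the statistical procedure, the parameters that matter, what
the synthetic cohort generator does and does not emulate, and the design
decisions taken where the design was genuinely open.

## The data model

The atom is an **event record**: one `(user_id, stream, timestamp, value)`
observation. Three streams matter to the analysis: heart rate (bpm, irregular
second-level timestamps), steps (counts per minute) and sleep stage (one of
eight device tokens: `asleep`, `awake`, `wake`, `light`, `deep`, `restless`,
`rem`, `unknown`). Timestamps are stored as UTC instants; a nominal per-user
timezone (default UTC) governs day boundaries. Labels are per-user binaries
(a clinical phenotype such as insulin resistance, and sex), with unknowns
explicit.

## De-identification by future anchoring

Each user receives one strictly positive random offset ("anchor") drawn
uniformly over a configurable range, and every timestamp of that user is
advanced by it. Within-user differences are therefore preserved *exactly* —
the time-series property the downstream features rely on — while absolute
dates and cross-user alignment are destroyed. Two design choices:

* **Whole-day offsets (default).** Feature extraction depends on within-day
  structure (sleep at night, activity by day). A sub-day shift would rotate a
  user's circadian profile relative to midnight and corrupt the day-split
  features, so offsets are whole days by default; second-granularity offsets
  remain available where that trade-off is acceptable.
* **Slight value noise.** Numeric streams optionally get zero-mean Gaussian
  noise (default sd 0.5 bpm for heart rate, 0 for steps; sleep categories are
  never touched). The default is chosen so that utility is demonstrably
  preserved: across a 20-user × 30-day synthetic cohort the cohort mean of
  every daily feature moves by well under 2% (the acceptance suite measures
  this). Step counts are re-clamped to non-negative integers after
  perturbation.

The anchor map is the re-identification key; `run_pipeline()` writes it under
a separate `keys/` directory, never alongside the de-identified events.

## Harmonization

Preprocessing is per user and strictly imputation-free:

1. **Sleep binarization.** `{asleep, light, deep, restless, rem}` → 1,
   `{awake, wake}` → 0, `unknown` → missing. The plain meaning of the tokens
   dictates this default; the mapping is an explicit function argument, so a
   study with device-specific semantics can swap it.
2. **1-minute grid.** Heart rate: mean of within-minute samples. Steps: sum
   (device steps are usually already minute-level). Sleep: 1 if any
   within-minute sample is asleep, else 0 if any is awake, else missing. The
   grid runs contiguously from each user-stream's first to last minute;
   sampling gaps are explicit `NA`s.
3. **Cleaning.** Heart-rate minutes strictly below `hr_floor = 20` bpm become
   missing ("below 20" is read literally: 20 itself is kept). Such values are
   sensor dropouts, not physiology.
4. **Smoothing.** Trailing (causal) rolling windows of `smooth_window = 5`
   minutes: mean for heart rate and steps, max for the binary sleep
   indicator. Trailing alignment is chosen because it is well defined at the
   series start (a partial window over the available prefix) and cannot use
   future data. Missing values are excluded from the window statistic, and a
   window that is missing everywhere stays missing — smoothing never turns
   absence into data. Cleaning precedes smoothing, so a sub-floor dropout
   cannot contaminate its neighbours' smoothed values.

The rolling statistics use a running-sum formulation (exact up to float
rounding, ~1e-16 relative) so that cohort-scale series (millions of minutes)
smooth in linear time. The rolling max is implemented for binary series —
its only use — and rejects other inputs.

## The 12 daily features

Days are split at local midnight; every non-missing minute belongs to exactly
one day. Within a day, heart-rate minutes are stratified by the concurrent
sleep indicator and step count:

* **sleeping**: minutes with sleep indicator 1;
* **resting**: minutes with step count 0 — read literally, so sleeping
  zero-step minutes are included; an `awake_only` flag provides the stricter
  variant (on the bundled generator the two coincide, because step events are
  only emitted while awake, so sleeping minutes have *missing* steps and drop
  out of the resting stratum either way);
* **active**: minutes with positive step count.

The 12 features are: mean overall / sleeping / resting / active heart rate,
the active−sleeping difference, total steps, sleep hours (count of
sleep-indicator-1 minutes / 60), and five outlier percentages — overall heart
rate, each stratum, and steps. This composition is the one consistent with
the enumerated items and the count of twelve; it is held in one place
(`user_feature_names()` derives from it) should a study need to vary it.

The outlier percentage of a set of values is
`100 · |{v : |v − mean| > k·sd}| / n` with `k = outlier_k = 2` and the sample
(n−1) standard deviation, computed **within the day** (features are defined
per day, so each day's own distribution is the reference; a constant set has
0% by convention, and an empty stratum propagates missing). A useful
closed-form check: any 2-point set has 0% outliers, because each point lies
exactly sd/√2 from the mean.

Degenerate-input conventions, chosen once and asserted in tests: an
empty stratum makes its mean and outlier features missing (and the
difference feature missing if either side is); a day whose sleep stream is
entirely absent gets *missing* sleep hours rather than 0, mirroring the
empty-stratum rule; a day with no data in any stream is skipped.

## User-level aggregation and cohort filters

Users without the target label are excluded, users with fewer than
`min_days = 14` usable days after preprocessing are excluded, and the
remainder are truncated to their first `horizon_days = 90` calendar days.
Seven statistics — mean, sample sd, min, max and the 25/50/75% quantiles
(linear interpolation, R type 7) — of each daily feature over the available
(non-missing) days give 84 features per user, named `stat__feature`.

## Classification

`cross_validate()` runs `cv_repeats = 10` repeats of a `cv_folds = 5`-fold
split of the **users** (plain random, matching the protocol; a stratified
flag exists). Within each fold:

1. missing user-level cells (a user can lack, say, active-HR statistics if
   they logged a no-steps day only) are imputed with the **train-fold**
   median;
2. a Yeo–Johnson power transform is fitted per feature on the training rows
   only — the exponent by profile maximum likelihood over λ ∈ [−5, 5]
   (`stats::optimize`), followed by centering/scaling to train mean 0, sd 1;
   constant columns pass through flagged;
3. an elastic-net logistic regression is fitted (glmnet) and the held-out
   users are scored.

All out-of-fold scores of a repeat are pooled into **one** AUROC
(Mann–Whitney formulation, ties half-credited) and **one** average precision
(step sum over descending unique thresholds), yielding 10 of each. Both
metrics are implemented directly and verified against brute-force oracles
(pairwise double loop; threshold sweep) in the test suite.

Leakage is a contract, not a hope: transform parameters, imputation medians
and coefficients of a fold are bit-identical under arbitrary mutation of the
held-out rows, and the acceptance suite asserts exactly that.

**Penalty convention.** The objective is average logistic loss plus
`λ(α‖β‖₁ + (1−α)/2‖β‖₂²)` with `α = l1_ratio = 0.5`. The protocol leaves the
regularization strength unspecified, so the package pins
`λ = 1/(strength · n_train)` with `regularization_strength = 1` — the
familiar inverse-strength C = 1 convention, a sensible default at this
cohort scale (n ≈ 20–30 users, 84 features: strong enough to prevent
separation blow-up, weak enough to let a real effect through). Under a fixed
λ the average-loss objective is invariant to duplicating every row, which
the tests assert; `strength` and an explicit `lambda` override are exposed,
and sensitivity to them should be reported in any real analysis.

## Embedding

For visualization, day-level vectors are filtered (days with zero total
steps removed — non-wear days — plus incomplete rows, since distances need
complete cases), transformed with a **signed log**, `sign(x)·log(1+|x|)`,
and standardized per column. The signed log is used because one feature (the
active−sleeping difference) is signed and counts can be 0, where a bare log
is undefined; it preserves order on all reals. A plain `log1p` flag exists
for nonnegative-only subsets.

The 2-D embedding itself is deliberately a **plug-in boundary**: it is
cited third-party methodology, not a contribution of this pipeline, and no
claim is made of reproducing any particular published geometry. The default
engine is non-metric MDS (`vegan::monoMDS`, seeded, initialized from
classical scaling) — a nonlinear neighbor-rank method that serves the same
visualization purpose; classical PCoA is the second engine, and the
interface (matrix in, per-day coordinates plus per-user coordinate-wise
medians out) is what any replacement must satisfy.

## The synthetic cohort generator

`generate_cohort()` is first-class, tested code — it defines the conditions
under which every downstream claim is verified. Per user it draws a profile
(sleeping < resting < active heart-rate levels around 54 / 65 / 92 bpm;
sleep onset ~22:30 ± 0.6 h, duration ~8 ± 0.5 h; mean daily steps
~8000 ± 2000; HR noise sd 2.5–4 bpm) and emits:

* heart-rate events every 30 s (second-level timestamps with a per-user
  phase), value = state level + white Gaussian noise, rounded to integer
  bpm;
* per-minute step events during awake minutes only, concentrated in
  Poisson-placed activity bouts (~18 min long, ~85 steps/min) calibrated to
  the profile's daily total; zeros are recorded between bouts;
* sleep-stage events every 60 s inside the nightly bout (sampling the five
  asleep-like tokens) and awake/wake markers every 5 min outside, with 1%
  `unknown`s.

Cases (phenotype = 1) get a configurable `rest_hr_delta` added to their
awake resting level (plus optional step and sleep-duration deltas); minutes
can be dropped independently at a configurable rate. Each user's RNG stream
derives from `(seed, user_id)`, so cohorts are byte-reproducible and
extensible without reshuffling existing users.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: heart-rate autocorrelation and circadian drift
within states (levels are piecewise constant), heart-rate response lag
around activity, inter-daily variability in sleep timing, device-specific
artifacts, and informative (non-random) missingness such as charging gaps.
The generator validates the *machinery* — contracts, leakage, determinism,
recoverability of a planted level shift — not clinical effect sizes.

## Problem sizes and verification

The package's own verification runs at sizes chosen to exercise cohort-scale
code paths while staying comfortably interactive: the acceptance suite uses
30 users × 60 days (≈ 8 million events) for the effect-recovery and null
checks, 20 × 30 for the de-identification utility bound, and an 8 × 16
pipeline run twice for byte-identity of the hash manifest. With an 8 bpm
resting-HR shift — about 1.8 between-user SDs in the generator — repeated-CV
mean AUROC comes out near 1 (≥ 0.7 required); with all effects zero it lands
in [0.4, 0.6] at the suite's fixed seed. Note that the pooled null AUROC of a
*single* 30-user cohort is a wide random variable across cohort draws — with
so few users, cross-validated models fit to noise can produce out-of-fold
rankings well below as well as above 0.5 — so the null band is a check at the
suite's fixed conditions, not a distributional guarantee. Determinism is asserted at file-hash level: the run manifest
(package version, config, seeds, MD5 of every artifact) is byte-identical
across reruns of a fixed config.

## Known limitations

* The resting stratum double-counts sleeping minutes whenever a device
  reports zero steps during sleep (the literal definition); use
  `awake_only = TRUE` if that is not wanted.
* Per-day outlier references make outlier percentages incomparable across
  days with very different coverage; a whole-record variant would need a
  different missing-data policy.
* The elastic-net regularization strength default is a convention, not a
  recovered value; report sensitivity in real analyses.
* Timezone handling supports one nominal zone per user; daylight-saving
  transitions shift the local midnight by an hour on two days a year.
* The embedding engine choice affects geometry; only seeded determinism and
  the coarse class-separation sanity property are guaranteed.
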