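---
title: "Decoding choice and outcome from trial-aligned calcium traces: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding choice and outcome from trial-aligned calcium traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prldecode)
```

## The problem this package addresses

During probabilistic reversal learning, an animal repeatedly chooses between
a left and a right option whose reward probabilities differ and reverse at
block boundaries. One-photon miniscope imaging yields, per session, a
detrended fluorescence trace for each neuron and a behavioural event table
for each committed trial. Three questions drive the analysis implemented
here:

1. How well do frontal-cortex population signals predict the upcoming
   **Chosen Side** and the **Trial Outcome**, moment by moment within a
   trial?
2. What fraction of single neurons is selective for side, outcome, or
   reward retrieval?
3. Do session-level behavioural strategies (win-stay, lose-shift,
   perseveration, flexibility) predict how decodable the population is?

Real recordings of this kind are expensive and animal-specific, so the
package ships a full forward model — task, choice agent, and calcium
traces — that generates sessions with *known* ground truth. Every analysis
stage is validated against data whose selective structure was planted.

## Task and agent simulation

`task_config()` encodes the session skeleton: 3 blocks of 75 committed
trials, the better side reversing at each boundary, and reward ratios per
schedule (100:0 → 90:10 for Schedule 1, 90:10 → 80:20 for Schedule 2,
80:20 → 70:30 for Schedule 3; the first pair applies to blocks 1–2 and the
second to block 3). Timing constants are seconds: 1 s reward delay after
the choice nosepoke, 5 s timeout after unrewarded choices, 10 s
inter-trial interval, and 40 s / 60 s initiation and choice deadlines.
Omitted trials are not simulated: all analyses operate on committed trials
only, so the generator produces exactly those.

The animal's choice process is not part of the experimental record being
emulated, so the package provides parametric agents spanning the relevant
behavioural regimes:

* `wsls` — stays after a win with probability `p_stay_after_win`, shifts
  after a loss with probability `p_shift_after_loss`. Setting both to 0.5
  gives a uniform random chooser; pushing them toward 1 gives a strongly
  strategy-driven animal. This lets cohorts be generated across the whole
  win-stay/lose-shift range, which the accuracy regressions need.
* `q_learning` — incremental value updates `V <- V + alpha * (r - V)` with
  a logistic (softmax) choice rule of inverse temperature `beta`.
* `forced_better` — deterministically picks the better side; useful for
  probing the programmed schedule itself (e.g. measuring that forced
  better-side choices in a 70:30 block are rewarded 70% of the time).

Latencies are drawn from log-normal distributions (strictly positive,
right-skewed, like real operant latencies), truncated at the deadlines.
All randomness in a call flows through its single `seed` argument;
sub-streams are derived deterministically, so a session is a pure function
of `(config, agent, seed)`.

## The calcium forward model

`generate_traces()` plants selectivity with a difference-of-exponentials
transient kernel (default rise 0.05 s, decay 0.5 s — a GCaMP6f-like
shape). For each selective cell, a transient is inserted at its locked
event on every trial with amplitude
`base_amplitude * (1 + modulation_depth * I[preferred condition])`;
non-selective cells contribute only spontaneous transients (a Poisson
process, default 0.05 events/s) and Gaussian noise. Output is
baseline-subtracted but not normalized, sampled at 20 frames/s, and the
noise-free component is exactly linear in `base_amplitude`.

One deliberate modelling choice needs flagging: `plant_population()` gives
side- and outcome-selective cells a default `event_offset` of −0.5 s, i.e.
their transients *anticipate* the locked event. Choice-predictive activity
in frontal cortex ramps up before the choice is physically executed — that
is precisely why decoding from the bin *before* the choice nosepoke is
informative. A transient inserted exactly at the anchor would, by the
kernel's causality, contribute almost nothing to pre-anchor bins, and
pre-event decoding of such a population would sit at chance no matter how
strong the planted modulation. The offset is a per-cell parameter, so
strictly reactive populations can be generated by setting it to zero.

What the generator does **not** emulate: slow drift and bleaching,
correlated (shared) noise across cells, trial-to-trial amplitude
variability, omissions, and cross-session cell identity. Passing tests on
this synthetic data therefore demonstrate the correctness and calibration
of the *analysis machinery* — not robustness to every artifact of real
recordings.

## Alignment and temporal binning

`extract_epoch()` cuts a fixed window around a named trial event — 4 s
centered on initiation, or 1 s before to 3 s after choice — taking the
nearest frame to the anchor timestamp (exact half-frame ties resolve to
the earlier frame, a deterministic convention). `bin_downsample()` then
averages overlapping 6-frame bins advanced by 2 frames (bin 1 = frames
1–6, bin 2 = frames 3–9, …), giving 38 bins for an 80-frame window.

`pre_event_bin()` returns the last bin wholly before the anchor: bin 8
(frames 15–20) for the choice window at 20 fps. For Trial Outcome analyses
the reference is the bin before the *reward cue*, which arrives 1 s after
choice; `pre_event_bin(epoch, offset = 1)` locates it (bin 18) inside the
same choice-aligned tensor. A bin is always a 6-frame average here; a
5-frame variant appears in some descriptions of this analysis style, but
the package uses the 6-frame definition consistently with its binning
rule.

Reward-retrieval activity is summarized by `retrieval_scalar_activity()`:
the mean over a window centered on reward-port head entry, spanning
`2 * half_width_frames` frames (default 10 → exactly 1 s at 20 fps; a
0.5 s window is available by passing `half_width_frames = 5`). Unrewarded
trials have no head entry, so a *pseudo-entry* is placed at
`choice + reward_delay + median(reward latency of the session's rewarded
trials)`: the same-width window at the time the animal would typically
have entered the port had it been rewarded. This anchoring rule for the
"corresponding window" is a design choice of this package; the median
latency centers the pseudo-window on the rewarded-trial entry
distribution.

## Balanced leave-one-trial-out decoding

For every trial `t` and bin `b`, `loo_decode()`:

1. excludes trial `t`;
2. draws `m` trials from each of the four side-by-outcome conditions
   (left-win, left-unrewarded, right-win, right-unrewarded), where `m` is
   the smallest remaining condition count — a fresh random draw per fold,
   so repeated folds sample the whole session;
3. trains a linear-kernel SVM (cost 1, no feature scaling — inputs are
   already detrended; both exposed as arguments) on the cells'
   bin-`b` activity;
4. predicts trial `t`'s label and tallies a 1/0.

Balancing makes the training priors exactly 0.5/0.5, so chance accuracy is
0.5 regardless of session-level label imbalance. All bins of a fold share
one balanced draw — trials are balanced, not bins. The per-fold weight
vectors are averaged into `weights`, oriented so that positive values are
evidence for the first label level (left / win). A test point falling
exactly on the hyperplane is resolved by a deterministic seeded coin.

If any condition is empty (e.g. a deterministic 100:0 session with no
losses on one side), the session is *not decodable* for that target and a
typed error is raised rather than silently unbalancing; callers can
restrict to blocks where both outcomes occur.

The shuffle null (`shuffle_null()`) reruns the whole procedure with the
label vector circularly shifted by a uniform random offset in `[1, N−1]`
(default; preserves label autocorrelation) or fully permuted
(`method = "permute"`). The number of repeats defaults to 100 and is a
parameter. `ablation_curve()` ranks cells by absolute decoder weight at
the pre-event bin and re-decodes after deleting the top `k` — on planted
data, removing exactly the signal cells returns accuracy to the chance
interval.

## Single-cell selectivity and heatmaps

`fit_cell_glm()` regresses a cell's per-trial scalar activity on the trial
labels by OLS: `activity ~ side` for Chosen Side, and
`activity ~ rewarded + side` for Trial Outcome and Reward Retrieval. The
side covariate in the outcome models prevents side-selective neurons from
masquerading as outcome-selective when side and reward are correlated (as
they inevitably are in a reversal task); the test suite demonstrates both
the controlled and the inflated (covariate-omitted) false-positive rate.
Selectivity is `p < 0.05`, uncorrected — the ratio of selective cells is
itself the quantity modelled downstream, and its calibration under the
null (fraction ≈ 0.05) is exactly what the uncorrected threshold
guarantees. Activity scalars are the pre-choice bin mean (side), the
pre-reward-cue bin mean (outcome), and the retrieval window scalar
(retrieval), matching the decoder's analysis bins. Cells with
zero-variance activity or a rank-deficient design (e.g. all trials on one
side) are unfittable and counted as non-selective in the denominator,
which is "all imaged neurons". Codings are 0/1 with L = 0; any consistent
binary coding yields identical p-values.

`peak_aligned_heatmap()` cross-validates its display: condition averages
are computed separately on odd and even trials, each cell's averages are
jointly range-normalized to [0, 1] (constant cells map to zero), the
difference (left − right, or unrewarded − rewarded) is formed, and the
peak location plus row order come from the odd trials while the *even*
trials are what gets displayed. Rows are ordered by signed selectivity
beta by default (most negative to most positive), with ordering by
odd-trial peak index available via `sort_by = "peak"` — both orderings are
used in practice for this figure style.

## Behavioural strategy metrics

With `N` trials per session:

* **Win-stay** = #(trials whose predecessor was rewarded and whose choice
  repeated) / (N − 1); **lose-shift** mirrors it with unrewarded
  predecessors and switched choices. The denominator is all trials with a
  predecessor, reading "proportion of all trials" literally; the
  conventional conditional proportions (denominator = post-win or
  post-loss trials) are available via `conditional = TRUE`.
* **Perseveration index** = mean number of trials to change side after the
  first unrewarded trial of a loss run. Runs unresolved at session end are
  censored at the remaining trial count rather than dropped (dropping
  would bias the index downward); `censor = FALSE` restores the dropping
  behaviour.
* **Flexibility index** = `mean(mean(m1, m2), mean(m2, m3))` where `m_b`
  is the block-`b` mean of the better-choice indicator.
* **Moving strategy traces**: per-trial win-stay/lose-shift indicators
  smoothed by a centered moving mean whose windows shrink at the session
  edges; the default width of 10 trials is a package choice (unstated in
  the analysis style this follows).
* **Latencies** are summarized as session medians; the reward latency
  median uses rewarded trials only.

## Session- and trial-level models

`build_choice_design()` stacks per-trial better-choice indicators with
TrialNum (the session's actual trial count), Block, Schedule, Session and
Area, coded 0 = OFC / 1 = M2 (and 0 = female / 1 = male, 0 = VEH / 1 = CNO
where those factors exist). `build_accuracy_design()` assembles one row
per session: decoding accuracy at the designated pre-event bin as the
response, with Area, Schedule, Session, NumCells, the strategy indices and
latency medians as predictors, plus optional Area-interaction columns.
`fit_glm()` fits by maximum likelihood — `lme4` with a per-subject random
intercept when the design has at least 3 subjects, plain `glm`/`lm`
otherwise (small synthetic cohorts cannot support a random effect), with
Wald normal-approximation p-values for the mixed fits. Rank-deficient
designs raise a typed error instead of silently dropping columns.

Because the interesting regression coefficients in real data depend on the
animals recorded, the package validates this module by *calibration and
recovery*: null designs produce |z| < 1.96 at the nominal rate, known
generating coefficients are covered by their Wald intervals, and a
synthetic cohort in which win-stay truly drives planted decodability
(modulation depth proportional to the agent's stay parameter) yields a
positive, significant WS coefficient.

## Numerical and degenerate-input conventions

* Anchor frames: nearest frame, half-frame ties to the earlier frame.
* Perfect (zero-residual) cell fits: a nonzero coefficient with zero
  standard error is assigned p = 0, an indeterminate one p = 1.
* SVM ties (decision value exactly 0): seeded deterministic coin.
* Degenerate SVM training sets that cannot be fit fall back to a seeded
  coin prediction with zero weights.
* Constant cells in heatmaps: normalized to all-zero rows.
* Sessions with no rewarded trials cannot anchor pseudo-entries and raise
  a typed error, as do sessions missing a side-by-outcome condition.

## Problem sizes used in the shipped validation

The test suite and acceptance script run entirely on simulated data at
sizes chosen to exercise each property clearly: 10,000 pooled block-3
trials for the schedule-probability check; 20 seeded sessions of 120
trials and 40 cells for decoder chance calibration; 1,000 null cells for
selectivity calibration; 10 seeds per planted fraction for recovery; 100
replicates of 800 observations for coefficient coverage; and 10 cohorts of
16 sessions (90 trials, 20 cells) for the strategy-accuracy regression.

## Known limitations

* The calcium model is phenomenological (kernel + noise), not
  biophysical; no spike inference is performed or supported.
* Shared noise and cross-session registration are out of scope, so
  population correlations in real data may degrade decoding in ways the
  synthetic validation does not probe.
* Mixed-model p-values use the normal approximation; for very small
  cohorts the fixed-effects fallback is deliberately preferred.
* The on-disk trace format is wide TSV; files for hour-long sessions with
  hundreds of cells are large, and callers holding such data should keep
  it in memory or chunk sessions.
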