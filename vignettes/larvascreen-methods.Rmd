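---
title: "Methods: simulating and analyzing a two-stage zebrafish antiseizure screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing a two-stage zebrafish antiseizure screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvascreen)
```

## The screening problem

Homozygous *scn1Lab* mutant zebrafish larvae model Dravet syndrome: from
about 4 days post-fertilization they show spontaneous behavioral seizures —
culminating in whole-body convulsions with high-velocity swim bursts of at
least 20 mm/s (Stage III on the three-stage scale: Stage 0, little or no
activity; Stage I, brief swim bouts; Stage II, rapid whirlpool-like
circling; Stage III, convulsions) — and epileptiform discharges in forebrain
field recordings. A phenotype-based screen exploits this: one mutant larva
per well of a 96-well plate, six fish per compound plus one six-fish row of
untreated internal controls, a 10-minute baseline locomotion recording, a
media change to drug (or fresh media for controls), and a second recording.
Compounds that suppress the seizure phenotype behaviorally are then
confirmed electrophysiologically.

`larvascreen` implements both analysis stages and a seeded synthetic-data
generator that reproduces the statistical structure this analysis relies
on, so every decision rule can be exercised against ground truth.

## Stage 1: locomotion and hit calling

For each fish the package computes distance traveled (mm), mean velocity
(distance over the epoch, mm/s), maximum instantaneous velocity, and the
active fraction of the epoch. The treatment effect measure is the percent
change in mean velocity between the two recordings,
$100\,(v_2 - v_1)/v_1$; velocity change is the more sensitive readout of
seizure behavior than distance, and the two coincide for equal epochs.

The hit threshold is not arbitrary: it is derived from the trial-to-trial
variability of untreated controls subjected to the same media-change
procedure. With the observed control percent-change SD of 21.8
(n = 112 fish pairs), two standard deviations rounded up to the next
integer percent gives the 44% threshold (`derive_threshold(21.8)` = 44).
A compound at one concentration is then classified with precedence
toxic > hyperexcitable > hit > inactive:

* **toxic** — at least 50% of the fish have neither heartbeat nor response
  to external stimulation at the 60-minute viability check;
* **hyperexcitable** — mean per-fish velocity change of at least +44%,
  and/or drug-induced Stage III in at least 50% of surviving fish;
* **hit** — mean per-fish velocity change of −44% or lower **and** Stage 0
  or I in at least 50% of surviving fish;
* **inactive** — everything else.

Dead fish are excluded from velocity means and stage counts; fish with zero
baseline velocity are excluded with a warning. Hits must be reproduced in a
second trial on an independent clutch, without a toxic call in either, to
advance (`confirm_hit()`).

Three points here were genuinely open and are decided by the package:

* *Mean versus per-fish velocity criterion.* The 44% decrease is applied to
  the mean of per-fish percent changes across surviving fish; requiring the
  threshold fish-wise is available via
  `hit_criteria(per_fish_velocity = TRUE)`. The mean is the default because
  the stage criterion already enforces a per-fish consistency check.
* *Precedence.* No compound ever receives two labels; toxicity is checked
  first because a dead fish's velocity is meaningless, and
  hyperexcitability before hit so that a proconvulsant with an aberrant
  velocity profile cannot be called a hit.
* *The Stage III clause of hyperexcitability.* Mutant larvae convulse
  spontaneously, so Stage III under treatment is, by itself, just the
  unperturbed phenotype; applied literally the clause would label nearly
  every non-suppressive compound hyperexcitable. The package therefore
  counts a fish toward this clause only if it was below Stage III at
  baseline (drug-*induced* convulsions); fish with unknown baseline stage
  always count. The +44% velocity arm is unaffected.

## Stage scoring

Stage III requires a sustained run of instantaneous velocity at or above
`stage3_velocity_threshold` (default 20 mm/s) lasting at least
`stage3_min_bout` (default 0.5 s; a single-frame spike is tracker noise,
not a convulsion). Otherwise stages 0/I/II are assigned by the active
fraction of the epoch (frames above 2 mm/s): Stage 0 at or below 5%,
Stage I at or below 25%, Stage II above. Operationalizing Stage II
("whirlpool-like" circling) as sustained high activity without
supra-threshold bursts is an approximation — circling geometry is not part
of the metric set — and is the weakest link of the scale; it does not
affect hit calling, which only needs the 0/I versus higher distinction and
the Stage III flag. Velocity uses raw per-frame Euclidean displacement with
no smoothing by default (tracker post-processing varies between rigs; a
centered moving average is available in `velocity_series()`).

## Stage 2: electrographic confirmation

Epileptiform events in a field recording are defined by rule: multispike or
polyspike deflections, upward or downward, exceeding three times the
baseline noise level for more than 500 ms. The implementation
(`detect_events()`):

* estimates the baseline noise as a robust SD, `1.4826 * mad(trace)` —
  insensitive to events occupying a minority of samples; the original
  workflow's manual noise reading is not recoverable, and a robust scale
  estimate is the standard automated substitute (`noise_multiple` is
  configurable precisely because "noise level" conventions differ);
* thresholds at ±`noise_multiple`·σ̂ and keeps supra-threshold excursions
  sustained for at least `min_excursion` (default 1 ms, i.e. two
  consecutive samples at 1 kHz). Without this debounce, isolated
  single-sample noise crossings (expected at a rate of about 2.7 per 1000
  samples at 3σ) chain into spurious >500 ms "events" at a rate of several
  per epoch; with it, chance events essentially vanish (the suite verifies
  at most 0.1 per 10-minute epoch over 100 seeds) while any deflection
  wider than a couple of samples is untouched;
* merges excursions separated by less than `spike_merge_gap` (default
  200 ms, chosen so the spike trains of a polyspike discharge group into
  one event) and measures the event extent from first to last
  supra-threshold sample;
* applies both gates strictly (> 3σ̂, > 500 ms) and requires at least two
  excursions (multispike).

Because the threshold scales with the estimated noise, detection is
invariant to rescaling the trace — amplifier gain cannot change the result.
The suite locates both gates by bisection: the duration gate flips within a
few milliseconds of 500 ms, and the amplitude gate within 2% of 3× the
noise estimate (the amplitude experiment injects into a noise-free window,
since otherwise noise adds to the spikes and shifts the flip point below
the gate).

A confirmed hit is tested for electrographic suppression: events per
10-minute epoch under drug versus the untreated mutant reference, with
`suppression_call()` requiring a reduction fraction of at least 0.9. The
literature quantifies "reduced to control levels" nowhere; 90% is a
declared convention of this package, reported alongside the raw counts so
the call can be re-judged at any other cutoff.

## The synthetic-data generator

`simulate_trajectory()` uses a two-state renewal model: quiescent drift
interrupted by brief swim bouts (Poisson onsets, default 30/min for
mutants, exponential durations of mean 0.3 s, speeds around 8 mm/s), with
Stage III bursts superimposed at their own Poisson rate (default 6/min,
1–2.5 s, 25 mm/s and never below the 20 mm/s convulsion threshold for
mutants; rate 0 for wild type). Slow movement is a heading-persistent
random walk reflected at the wall of a 6.4 mm square well; burst movement
is rendered as tight circular swimming inside the well so that
frame-to-frame displacement stays at the burst speed — a convulsing larva
cannot translate at 25 mm/s for a second inside a 6.4 mm well, and the
circular rendering is also a reasonable cartoon of whirlpool-like seizure
swimming. Gaussian positional jitter (0.01 mm) models tracker noise. The
default sampling rate is 25 Hz and the arena is well-sized; neither is
stated by the source screen (typical larval tracking rigs run 25–30
frames/s), both are configurable, and no result in this package depends on
their exact values.

Trial-to-trial variability — the quantity that sets the screen's detection
threshold — is modeled as a per-recording multiplicative lognormal factor
on all speeds. Its sigma is set from the target percent-change SD
(`trial_variability_sd`, default 21.8) after subtracting the intrinsic
bout/burst counting variability of a 600 s recording; the intrinsic
constant (0.0772 on the log scale) was fixed once by simulation. With
defaults, the sample SD of percent change across 112 simulated control
pairs averages 21.8 (±0.3 SE over 60 replicate screens at calibration
time; the acceptance suite re-checks 21.8 ± 1.0 over 200 independent
replicates). Because the factor is multiplicative, the percent-change
distribution is mildly right-skewed: its suppression tail at −44% is
*lighter* than the Gaussian 2.28% one-sided tail (about 0.2% per fish,
effectively zero at the six-fish trial level), so the control-derived
threshold is, if anything, conservative on this generator.

`simulate_lfp()` produces Gaussian baseline noise (default 10 µV) with
injected polyspike events: trains of 50 ms biphasic spikes under a shared
extent of 1–3 s at 6× noise, spaced closely enough that the default
detector merges each train into one event, with first and last threshold
crossings aligned analytically to the nominal extent (which is what makes
millisecond-resolution boundary bisection possible). The Poisson event
count is preserved exactly by placing events via uniform spacings of the
free time, keeping them non-overlapping and at least 600 ms apart.
Interictal spikes — isolated sub-500 ms transients at 4/min — are injected
as distractors and excluded from ground truth; optional 1/f background is
deliberately omitted (white noise keeps the noise-estimate oracle exact;
robustness to colored noise is untested and a known limitation). The
default untreated mutant event rate is 2/min (≈20 events per 10-minute
epoch), a plausible mid-range figure for this preparation; wild-type
parameters would set it near zero.

Drug effects are four multipliers with class presets: suppressive
(velocity ×0.3, bursts ×0, LFP events ×0.05), toxic (kills: viability
flags false, movement flattened), proconvulsant (velocity ×1.6, bursts and
LFP events ×2), inert (all ×1), and behavioral false positive (velocity
and bursts suppressed like a sedative but LFP events ×1 — the class the
second stage exists to catch). Default class frequencies in
`simulate_screen()` (2% suppressive, 15.2% toxic, 5.4% proconvulsant,
0.3% behavioral false positive) mirror the outcome proportions of a
repurposed clinical library.

What the generator does **not** emulate: circling geometry (Stage II is
scored from activity, see above), posture loss, dose–response (one
concentration per trial object; concentration series are just multiple
trials), the 15–30 min drug equilibration period, plate-position or
day-of-experiment batch effects (control variability is pooled, not
structured), colored LFP noise, and electrode placement variation.
Passing tests therefore show that the decision rules are implemented
faithfully and recover planted effects under realistic variability — not
that the pipeline is robust to every artifact of real tracking or
electrophysiology data.

## The funnel and its summary

`run_screen()` chains the stages: simulate the library → derive the
threshold from the screen's own pooled controls → classify every compound
(trial 1) → retest trial-1 hits on an independent clutch → run
electrophysiology (six fish per compound) on confirmed hits only, as in
the original funnel (`ephys_on_all = TRUE` lifts this for methods
studies). `funnel_summary()` enforces the conservation invariant
(hits + toxic + hyperexcitable + inactive = tested) and reports the hit
rate in percent **truncated** to two decimals — 20 of 1012 prints as
1.97, which rounding would give as 1.98. Every run logs its seed,
threshold, and gate settings (`run_log.json`).

## Numerical choices and degenerate inputs

* 2·SD thresholds are rounded *up* to the next integer percent
  (ceil(43.6) = 44), matching the printed threshold.
* "At least 50% of six fish" is a weak inequality: 3 of 6 qualifies.
* Both detector gates are strict (> 3σ̂, > 500 ms); boundary samples are
  excluded. Excursions separated by exactly the merge gap are not merged.
* Bisections in tests and the acceptance analysis run to 1 ms
  (duration), 10⁻⁴ mm/s (stage velocity), and 0.005σ (amplitude).
* Constant LFP traces have zero estimated noise and are refused by
  detection rather than silently dividing by zero; trajectories need at
  least two samples with strictly increasing timestamps; control
  variability needs at least two valid pairs; percent change is undefined
  for a zero-velocity baseline and such fish are excluded and flagged.
* All generators are pure functions of (parameters, seed); with
  `seed = NULL` they consume the current RNG stream so that compound
  objects (plates, screens) are reproducible from a single top-level seed.

## Problem sizes used in validation

The validation suite runs distributional checks at sizes chosen to give
stable estimates: the control-variability calibration at the study design
size (112 pairs) over 200 replicate screens; event-count Poisson moments
over 200 traces; event recovery (≥5σ, ≥700 ms: at least 95% recovered with
extents within the merge gap of ground truth) over 100 traces; false
positives on pure noise over 100 traces; the planted-compound funnel
(one suppressor and one behavioral false positive against ten inert
compounds, full two-trial confirmation and six-fish electrophysiology)
over 20 screens; and label recovery over 20 screens of 48 compounds at
the default class frequencies, pooling ≥40 suppressive and ≥140 toxic
compounds for the sensitivity estimates. Full-size 1012-compound screens
run identically (about two minutes each) and are exercised through the
command-line interface rather than the routine test suite.

## Known limitations

* The Stage II operationalization is activity-based, not geometric.
* The 90% suppression cutoff is a convention; real calls should weigh the
  reported raw counts.
* The noise model is white; MAD-based noise estimation under strong 1/f
  background would need a detrending step that is out of scope.
* The generator's drug effects are stationary multipliers: no
  equilibration kinetics, no within-trial drift, no partial penetrance
  across fish.
* Multi-plate normalization beyond pooled control variability (e.g.
  B-scores) is out of scope, as is dose–response fitting.
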