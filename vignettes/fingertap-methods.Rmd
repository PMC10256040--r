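---
title: "Methods: automated finger-tapping assessment from index-finger accelerometry"
author: "fingertap package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated finger-tapping assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fingertap)
```

## The problem

Bradykinesia — slowness and smallness of movement — is a cardinal motor sign
of Parkinson's disease, and the finger-tapping item of the UPDRS motor exam
(Part III, Item 3.4) is its standard clinical probe: the patient taps index
finger on thumb "as largely and quickly as possible" for about ten seconds,
and an expert rates the performance 0 (normal) to 4 (can barely perform),
judging amplitude, speed, hesitations and decrement. Expert ratings are
subjective and poorly reproducible; this package automates them from a single
tri-axial accelerometer worn on the distal index finger.

The pipeline has five stages: preprocessing, tapping-block detection,
single-tap detection, kinematic feature extraction, and score prediction,
plus the statistical battery used to validate predictions and a synthetic
signal generator that makes every stage testable without patient data.

## Preprocessing

Recordings arrive at 250–5000 Hz, in g or m/s², possibly with the sensor
mounted upside down, with 50 Hz line noise and with movement artifacts.
`preprocess_trace()` normalizes all of this:

* **Resampling to 250 Hz.** Band-limited (Fourier-domain) resampling,
  applied identically per axis. This is ideally anti-aliased and exact for
  band-limited content; rates below 250 Hz are refused rather than
  upsampled. 250 Hz retains ample resolution for tapping at 1–5 taps/s.
* **Unit control.** A resting accelerometer reads 1 g of static gravity, so
  a median signal-vector magnitude (SVM) in [5, 15] raw units implies SI
  units; such traces are divided by 9.80665.
* **Band-pass 2–48 Hz with a 50 Hz notch.** A 4th-order Butterworth applied
  forward–backward (zero phase, so impact-peak timing is not shifted)
  detrends the signal and removes gravity. Band edges alone leave ~8 dB at
  exactly 50 Hz, so line noise is removed by a dedicated zero-phase
  second-order notch (Q = 35), giving > 40 dB suppression at the line
  frequency while leaving 2–47 Hz essentially untouched. Signals are
  padded by odd extension before filtering so the filter's settling
  transient does not ring into the trace (a static gravity step would
  otherwise masquerade as activity at the recording edges).
* **Orientation.** On the dominant-variance axis, impact peaks of a
  correctly mounted sensor are extreme *positive* excursions. If the 1st
  percentile magnitude exceeds 1.5 × the 99th percentile magnitude, the
  mounting was inverted and all axes are negated.
* **Artifacts.** Per axis, samples with |value| > 10 × the 99th percentile
  of |values| are flagged and linearly interpolated, keeping downstream
  arithmetic finite while the mask records what was replaced. A guard pass
  with the same rule runs in the raw domain *before* resampling, because a
  single extreme spike would otherwise be smeared across the trace by
  band-limited resampling and inflate the tap-detection threshold, which is
  proportional to the block maximum.

Running the chain twice leaves every decision unchanged (no re-flip, no
re-scaling, no new artifact flags); the filtered signal itself changes below
the percent level on the second pass, as any real band-pass applied twice
must, which is why idempotence is asserted on decisions and on detected taps
rather than bit-for-bit on samples.

## Tapping-block detection

The SVM series (per-sample `sqrt(x² + y² + z²)`) is segmented into eight
non-overlapping 125 ms segments per second — realized as alternating 31/32
sample segments at 250 Hz so that eight segments tile each second exactly.
Each segment's *activity percentage* is the share of samples above an
activity threshold: 0.5 × the standard deviation of the full SVM series.
Non-overlapping windows of ten segments (1.25 s) are labelled active when
more than two segments exceed 30% activity; active windows closer than 2 s
are merged (to fixpoint) and surviving intervals shorter than 0.32 s are
discarded.

Two package-level refinements:

* **Noise floor.** On a trace with no tapping at all, 0.5 × sd collapses to
  the sensor noise level and everything becomes "active". The threshold is
  therefore floored at 2.5 × the SVM median. The median is dominated by
  rest in protocol-compliant recordings (blocks are preceded and separated
  by ≥ 10 s of rest), making it a self-calibrating noise-envelope estimate:
  on pure noise the floor sits near the 99.9th percentile of the noise
  distribution, while remaining far below tap amplitudes even in severe
  bradykinesia.
* **Boundary refinement.** Window-level labelling quantizes block bounds to
  the 1.25 s grid. After merging, each bound is refined outward at segment
  (125 ms) resolution, bridging inactive runs shorter than the same 2 s
  merge gap. This reuses the existing activity definition — it only removes
  the window quantization.

## Single-tap detection

Each index-finger-on-thumb contact produces a sharp positive "impact" peak
(the contact deceleration). Within a block, impacts are SVM local maxima
that (1) exceed 20% of the block SVM maximum, (2) show a steep rise and
fall: the first difference exceeds +20% of its maximum somewhere in the
half-refractory window before the peak and falls below 20% of its minimum
after it, and (3) respect a 166 ms refractory period, resolved by keeping
the higher of two competing peaks. The half-refractory extent of the
differential criterion is a package choice (the rule's temporal window is
otherwise unspecified) and is exposed in the configuration.

A tap spans impact-to-impact; the last tap ends at the block end. The
finger-opening ("raise") window starts at the first positive excursion of
the dominant-variance axis after the impact transient returns to zero and
ends at that excursion's first zero-crossing, capped at 0.5 s; taps whose
raise cannot be delineated are kept with the raise-derived features marked
undefined.

## Kinematic features

Per block: total tap count, tapping frequency (taps/s), mean tap duration,
duration-normalized SVM RMS, amplitude-histogram Shannon entropy (64
equal-width bins, in bits), and jerkiness — the rate of directional changes
of acceleration (sign changes of the first difference per second; the
count-rate reading is used, not a third derivative, because a count is what
"number of directional changes" defines). Per tap: inter-tap interval,
normalized RMS of the tap, RMS in a ±40 ms window around the impact, peak
raise velocity (trapezoidal integral of raise-window acceleration × 9.80665,
maximum of the running integral, in m/s), jerkiness and entropy. Each
per-tap feature is aggregated as mean, coefficient of variation (population
sd / mean) and *decrement* — the OLS slope against tap start time, the
within-block fade that is characteristic of parkinsonian tapping; for
entropy and ITI the absolute slope is used. Aggregates are computed over
the first 15 detected taps by default (configurable to all taps); the raw
tap count always reflects every detected tap because the rule layer depends
on it. Degenerate inputs (no taps, zero-mean features, fewer than two valid
values) yield explicit NA markers, which the classifier median-imputes with
medians derived from training data only.

## Score prediction

Prediction is hierarchical. Blocks with fewer than nine detected taps are
handled by rules: if the block's normalized RMS falls below the 10th
percentile of few-tap training blocks the block scores 4 (barely any
movement); if its mean raise velocity exceeds an empirically defined
threshold the block is returned to the classifier (few but well-performed
taps); otherwise it scores 3, mirroring the UPDRS reading of severe
decrement or very slow movement. The velocity threshold is defined as the
training-set median of mean raise velocity among blocks scored 0 or 1 — an
operationalization of "well-performed" chosen here because no value is
published; it is configurable. All remaining blocks are classified into
0–3 by a 1000-tree random forest with class-frequency-balanced priors and a
fixed seed (score-4 blocks are excluded from classifier training; they are
reachable only through the rule). Ordinality is deliberately ignored — the
problem is treated as plain multiclass.

Model development uses a subject-exclusive 75/25 split found by randomized
search: whole subjects are assigned to one side, and a split is accepted
when per-class score proportions and site proportions on both sides are
within 0.03 of the full-cohort proportions and the block-count ratio is
within 7% of 75/25. Five-fold score-stratified cross-validation metrics are
recorded during training; the final model is fitted on the full development
set. Imputation medians and both rule thresholds come from development data
only, so no information leaks from the holdout.

## Statistical evaluation

The battery reports the mean absolute prediction error in raw score units,
ICC(3,k) — two-way mixed-effects, consistency, average-measures, computed
from the ANOVA mean squares with blocks as targets and {expert, model} as
the k = 2 raters — the Pearson correlation, and the multiclass confusion
matrix. Significance uses a random-labels permutation test: the true-label
vector is shuffled (n = 1000, preserving the score distribution) and the
metric recomputed against fixed predictions; p = (1 + #extreme)/(n + 1)
with direction ≥ for skill metrics and ≤ for error metrics, so p can never
be 0. Per-subject Pearson correlations are reported with explicit NA for
subjects whose true scores do not vary. Feature–condition contrasts use
two-sided Mann-Whitney U (exact for tie-free groups with min n ≤ 8,
tie-corrected normal approximation otherwise) with Bonferroni correction.
Random-forest feature importance is mean decrease impurity, normalized to
sum to 1.

## The synthetic generator

`generate_recording()` emulates the clinical protocol: 10 s tapping blocks
preceded and separated by ≥ 10 s of rest, baseline noise (sd 0.015 g per
axis) and a 1 g gravity offset on one axis. Each tap is a parametric
waveform on the dominant axis — a ≤ 30 ms half-sine impact transient, a
positive half-sine raise and a negative half-sine closing — with the other
axes as attenuated (0.2–0.5×) copies plus noise. This morphology was chosen
over recorded templates because it is fully parametric and closed-form
checkable (the raise integral has an analytic value). Severity profiles
0–4 jointly move tap rate (3.8 → 0.6 taps/s), impact amplitude (2.2 →
0.07 g), raise amplitude, ITI jitter (cv 0.05 → 0.5), per-second amplitude
decrement and hesitation probability (0 → 0.5), monotonically in the
clinical direction; severity 4 produces fewer than nine near-noise taps per
block. Acquisition quirks — output rate up to 5000 Hz, SI units, inverted
mounting, 50 Hz line noise, artifact spikes — are independently togglable.
All per-tap schedules and amplitudes are drawn before any rate-dependent
noise, so recordings generated at different rates from one seed share
identical taps and ground truth.

`generate_cohort()` adds cohort structure: subject base severities are
allocated by largest-remainder rounding from the class mix (default
0: 11.6%, 1: 42.2%, 2: 30.9%, 3: 15.3%, the naturally unbalanced clinical
distribution), blocks fluctuate ±1 severity with probability 0.1 per side
(clamped to 0–3) across cycling med/stim ON/OFF condition tags, and the
base prior is pre-compensated through the shift-transition matrix so the
block-label marginal matches the requested mix. Subject identity therefore
carries real information and subject-exclusive splitting matters. The
default test cohort is 36 subjects × 10 blocks (~360 blocks), sized to
mirror a realistic clinical study while keeping a full pipeline run around
half a minute.

What passing tests on this generator do **not** show: the waveforms carry
no tremor superposition, no sensor drift, no within-block postural noise,
and the severity-feature mapping is by construction monotone. Synthetic
results therefore validate the machinery — detection geometry, feature
definitions, split hygiene, statistical calibration — not clinical accuracy
on real patients.

## Numerical choices and degenerate inputs

* Intervals are 1-based half-open `[start, end)` sample indices; ground
  truth and outputs use seconds, which are representation-free.
* Filter: order 4 (per band), zero-phase; traces shorter than three times
  the 2 Hz impulse-response scale (375 samples) are refused.
* Threshold readings: "more than two segments" is ≥ 3; "closer than 2 s"
  and "shorter than 0.32 s" are strict; "20th percentile of the maximum"
  is 0.20 × max (a scalar has no percentile); refractory ties keep the
  higher peak.
* Entropy uses equal-width binning over the observed range; a constant
  signal scores 0. CoefVar uses population sd; a zero-mean feature yields
  NA. Permutation p-values use the add-one convention.
* The impact-RMS half-width (40 ms) is kept below half the refractory
  period so impact windows of adjacent taps cannot overlap.

## Known limitations

The severity profiles and noise levels are package choices on top of the
published protocol constants; real cohorts will differ. Block detection can
truncate or split blocks whose final seconds contain a multi-second freeze —
by construction, since gaps longer than the 2 s merge rule are genuine
inactivity. The score-4 rule is pragmatic and reachable only through the
few-taps path, matching its intended use for screening rather than
validated grading. The classifier treats scores as unordered classes; no
posterior calibration is attempted.
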