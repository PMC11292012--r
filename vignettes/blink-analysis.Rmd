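---
title: "Methods: blink detection and clinimetric summaries from EAR traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blink detection and clinimetric summaries from EAR traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blinkr)
```

This vignette documents the models, estimators and design choices behind
`blinkr` — what is computed, why it is computed that way, and what the
synthetic validation does and does not demonstrate.

## Signal model

The pipeline's central object is the per-eye EAR trace: the eye aspect
ratio sampled once per video frame (typically 240 fps). EAR is the ratio of
the mean vertical lid-landmark separation to the horizontal corner
distance, so it is dimensionless and invariant to head–camera distance; an
open adult eye sits around 0.25–0.35 and full closure approaches 0. The
pipeline starts at landmark tables: face detection and mesh-landmark
regression belong to an upstream front end, and any depth coordinate such a
front end exports is ignored — the EAR is a planar, image-space quantity.

Frames with unusable landmarks are not dropped: they become gap samples,
filled by linear interpolation between the nearest valid neighbours (edge
gaps held at the nearest valid value) and flagged in a gap mask. Detection
therefore never sees missing samples, while QC can still report the gap
fraction per eye.

## Blink detection

Blinks are transient dips of the EAR below the subject's own openness
level. Because that level differs between eyes (a narrowed paretic fissure
has a lower resting EAR) and drifts within a 20-minute recording, all
thresholds are *relative to a local baseline* rather than absolute.

1. **Smoothing.** Centred moving average, window `smooth_window_ms`
   (default 25 ms ≈ 6 samples at 240 fps). Edges use the partial window, so
   constants are preserved and length is conserved.
2. **Baseline.** Rolling upper percentile (`baseline_percentile`, default
   75, over `baseline_window_s`, default 30 s) of the smoothed trace.
   Blinks occupy a few percent of any window, so an upper percentile tracks
   the open-eye level while ignoring the dips.
3. **Hysteresis state machine.** A candidate opens when the smoothed EAR is
   at or below `theta_p × baseline` (default `theta_p` = 0.7) and closes
   when it recovers to at least `hysteresis_fraction × baseline` (default
   0.85). The two levels prevent chatter when the signal hovers near the
   counting threshold; a partial re-opening that does not clear the release
   level stays part of the same blink.
4. **Crossing measurement.** Onset and offset are the first down-crossing
   and last up-crossing of the counting level inside the candidate,
   linearly interpolated between samples; duration is the full width at
   that level. Ties at a threshold resolve toward closure (`≤`).
5. **Post-processing.** Candidates closer than `merge_gap_ms` (50 ms) are
   merged (minimum EAR over the parts); durations outside
   `[min_duration_ms, max_duration_ms]` (33 ms — about 8 samples at
   240 fps, rejecting single-sample noise — to 2 s, excluding sustained
   closures) are discarded. Candidates that begin on the first sample or
   never release before the trace ends have no interpolable crossing and
   are dropped.

Every returned event is *counted* by construction (it reached
`theta_p × baseline`, a proxy for "at least the pupil covered");
it is additionally *complete* when its minimum EAR is at or below the
absolute threshold `theta_c` (default 0.10 — low enough that a narrowed
but fully closing synkinetic eye classifies complete, high enough that the
acute-palsy closure floor around 0.13 does not).

### Why the thresholds are measured against a second, median baseline

The upper-percentile baseline is the right tool for *finding* blinks — it
is insensitive to the dips themselves — but it is a biased estimate of the
open-eye level: the 75th percentile of (open level + noise + drift spread)
sits a fraction of a standard deviation *above* the true level. For a
fast, deep healthy blink this hardly matters; for the slow, shallow
waveform of an acutely paretic eye, the measured width at the counting
level is several times more sensitive to the level, and the bias inflates
durations by tens of milliseconds. `detect_blinks()` therefore runs two
passes: candidates are detected against the p75 baseline, those samples
(plus a 50 ms margin) are masked out, and the final thresholds are
re-derived from a rolling *median* of the remaining blink-free samples —
an unbiased location estimate under symmetric noise. The refinement
changes healthy durations by under a millisecond but removes a
~15 ms inflation on slow paretic blinks.

Eyes are processed independently; inter-eye synchrony of blinking is out
of scope.

### Numerical choices

* The rolling percentile is evaluated on a ~60 Hz decimated view of the
  trace with a 1 s stride and linearly interpolated to every sample. A
  30 s window still contains ~1800 samples, so the window percentile is
  statistically unchanged, and the cost on 288 000-sample recordings drops
  by more than an order of magnitude. Everything stays deterministic.
* An all-zero trace yields an all-zero baseline with a warning and no
  counted blinks — a recording of a closed eye is not an error.
* Degenerate landmark geometry (coincident eye corners) is an error for a
  single landmark set and an invalid frame (gap sample) in a table.

## Per-eye summaries

* `avg_ear` — mean of the smoothed EAR over the union of the *first 3 s of
  every blink-free interval* (intervals shorter than 3 s contribute
  wholly). Sampling right after each blink avoids the slow lid drooping
  that accumulates late in long inter-blink intervals.
* `min_ear` / `max_ear` — recording-global extrema of the smoothed trace.
  Published group tables are ambiguous about whether "minimum EAR" is the
  recording-global minimum or a per-blink statistic (a synkinetic eye with
  some complete closures cannot have a global minimum of 0.06); both
  readings are reported — the global minimum as the headline, the mean of
  per-blink minima as `min_ear_blinkmean`.
* Counts are normalised to 20 minutes (`count × 1200 / duration_s`) so
  recordings deviating from the 20-minute protocol stay comparable;
  frequency is per minute. Mean durations of an empty event set are `NA`,
  never 0.
* The per-minute time course bins events by onset into half-open
  `[60(k−1), 60k)` bins; an onset exactly on a boundary belongs to the
  later bin.

The palpebral fissure height ratio (paretic/contralateral, percent) is the
ratio of *medians* of the per-frame fissure heights over blink-free frames
(frames inside any blink of either eye are excluded). The median makes the
estimate robust to residual blink contamination; for two eyes whose
geometry differs by a pure scale factor it is exact.

## Group statistics

Side comparisons are paired Wilcoxon signed-rank tests (zero differences
dropped, ties mid-ranked; at least five non-zero differences required).
Healthy controls have no paretic side, so a fixed convention aligns them:
healthy left ↔ paretic-like, healthy right ↔ contralateral-like. Three-group
comparisons are classic equal-variance one-way ANOVAs with Welch pairwise
post-hocs, Bonferroni-corrected by the factor 3 and capped at 1. PROM
correlations are Spearman's rho with no multiplicity correction — they are
exploratory, and the report tables say so via the `adjusted` flag. The
significance threshold is fixed at 0.05 throughout; no FDR control
anywhere. PROM instruments themselves are not implemented: domain scores
enter as already-scored numbers.

A whole-report failure mode is distinguished from a parameter-level one:
requesting a three-group report with fewer than two subjects in a group is
a cohort error, while a single parameter that is missing for a whole group
(e.g. no blinks, hence no mean duration) yields `NA` p-values without
aborting the report.

## The synthetic generator

The generator works at EAR level — it emulates the *signal*, not the
video. Per eye:

* **Onsets** follow a renewal process: a 0.5 s refractory period plus an
  exponential extra gap whose mean is set so the process matches the
  preset's blink rate. This is the simplest renewal model matching a mean
  rate; real inter-blink intervals are over-dispersed relative to it, so
  minute-to-minute count variability in real data is larger than the
  generator's.
* **Waveform**: each blink is a raised-cosine dip from the local (drifting)
  baseline to its floor — the complete-closure floor with probability
  `p_complete`, else the subject-level partial floor — scaled so that its
  full width at the counting level `theta_p × local baseline` equals the
  drawn duration. Generator and detector thus speak the same duration
  language, and recovery error measures the estimator, not a definition
  mismatch. Durations are normal, truncated at 60 ms.
* **Nuisance structure**: a zero-mean sinusoidal baseline drift (amplitude
  0.02 EAR, period 300 s) exercises the rolling baseline; additive Gaussian
  sample noise (σ = 0.01 EAR) is calibrated so the default detector has
  zero false positives on blink-free traces; occasional raised-cosine
  wide-opening excursions give the max-EAR statistic something to find.
  The signal is clamped at 0. Blink supports never overlap: an onset whose
  waveform would intrude on the previous blink is pushed forward past it,
  so ground truth and detection can be matched one-to-one.
* **Floors** are subject-level constants: the recording-global minimum EAR
  then recovers the preset floor. (Per-blink floor variability would bias
  the global minimum downward — one reason the global minimum should be
  read with care; see the estimator note above. Under measurement noise the
  global minimum still sits slightly *below* the floor, by the expected
  minimum of the smoothed noise over all near-floor samples — about 0.01
  EAR at the default noise level.)

The five presets encode the published group profiles (open-eye baseline,
rate, duration, complete-closure share, floors) of healthy, acute-palsy
paretic/contralateral and synkinesis paretic/contralateral eyes of
20-minute 240 fps recordings. The acute paretic preset generates *no*
complete closures: its published complete-closure frequency (0.5/min,
median 0) coexists with a minimum-EAR of 0.13 only under a per-subject
reading; at trace level the two are mutually exclusive, and the preset
follows the minimum-EAR profile. The synkinesis partial floor (0.10) sits
exactly at `theta_c`, so the complete flag of partial synkinetic blinks is
a noise coin-flip by construction — the validation checks flag agreement
only for floors clear of the threshold.

`fissure_scale` is each condition's palpebral fissure height relative to a
healthy eye (0.96 acute, 0.88 synkinesis). `emit_landmarks()` applies it as
a *uniform* scale of the six-landmark geometry: the scale-invariant EAR is
reproduced exactly while absolute fissure heights scale linearly — which is
the only geometry satisfying both requirements at once.

Cohorts add a subject-level lognormal blink-rate multiplier (sdlog 0.7,
mean 1) shared by both eyes: spontaneous blink rates vary enormously
between people, paired side comparisons should not profit from that
between-subject variance, and the optional `coupling` knob needs
subject-level heterogeneity to inject a monotone blink–PROM dependence for
power-testing the correlation analysis. PROM scores are truncated normals
at the instrument bounds (FaCE domains 0–100, FDI physical −25–100),
independent of blinking by default.

## What the validation shows — and what it does not

The test suite checks, on synthetic recordings at the study conditions
(20 min, 240 fps, ten seeds per preset), that the pipeline *recovers the
parameters the generator was given*: rates within 5 % relative, mean
durations within ±10 ms, EAR levels within ±0.02; that the detector
exactly matches a brute-force threshold scan on hundreds of randomized
dip traces; that the paired Wilcoxon and the ANOVA hold their nominal
type-I error (within [0.03, 0.07] at 2000 null replicates); and that a
full 30/6/24 synthetic cohort reproduces the qualitative clinical picture
(reduced paretic-side frequency in both patient groups, no healthy side
difference). Statistical-convergence checks use 10 seeds at 300 s vs
1200 s; the recording-global minimum EAR is excluded from convergence
testing because an extreme statistic drifts with recording length rather
than converging.

Passing these tests shows the estimators are calibrated against the
generative model — not that the model captures everything in real videos.
Real EAR traces contain landmark-tracking dropouts in bursts, non-Gaussian
heavy-tailed noise, head-pose-induced EAR modulation, over-dispersed blink
timing and blink doublets; none of these are in the generator. The gap
mask, the relative thresholds and the hysteresis are designed for those
phenomena, but their effectiveness on real recordings must be established
on real recordings.

## Known limitations

* Blink kinematics beyond duration (peak closing velocity, amplitude) and
  inter-eye synchrony are not computed.
* Voluntary and reflex blink paradigms are outside the model; the presets
  describe spontaneous blinking at rest.
* The detector's duration retains a small positive bias (< 10 ms on the
  slowest waveforms) from noise-induced outer threshold crossings and
  smoothing; it is visible in the recovery tests and bounded by their
  tolerances.
* Sample-size planning utilities are deliberately absent.
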