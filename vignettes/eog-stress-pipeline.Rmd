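---
title: "Detecting stress from eyewear EOG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting stress from eyewear EOG: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eogstress)
```

## The problem

Electrooculography (EOG) records the corneo-retinal standing potential with
skin electrodes; blinks appear as large, stereotyped deflections on the
vertical channel and saccades as step-like deflections on both channels.
Blink statistics — rate, duration, amplitude — shift under cognitive load,
so a pair of sensor-equipped glasses sampling EOG at 50 Hz together with a
3-axis accelerometer is enough, in principle, to monitor mental stress
during screen-based work. `eogstress` implements that idea as a complete,
testable pipeline: signal cleaning, blink detection by template matching,
sliding-window feature extraction, Lasso feature selection, and supervised
classification of 3 s windows into stress states, validated by stratified
10-fold and leave-one-subject-out (LOSO) cross-validation.

Because no public recording of this kind is available, the package ships a
first-class synthetic-data generator with ground-truth annotations. Every
stage is tested against that ground truth, and the whole pipeline runs
end-to-end on a purely synthetic cohort.

## The synthetic cohort: what it emulates

`synth_config()` describes a 12-subject study. Each session lasts 884 s: a
120 s baseline rest, then four tasks of 101 s, each of the first three
followed by a 120 s relaxation interval. The rests are fixed at two minutes
by the emulated protocol; task lengths are not printed anywhere for the
original study, so we chose equal task durations that make the session total
884 s — the length at which a 3 s window sliding by 1 s produces exactly 882
windows per subject. Each task carries a ground-truth stress state and a
0–4 Likert self-report consistent with it (tasks 1–2: level-1 stress,
ratings 2–3; tasks 3–4: level-2 stress, rating 4).

The vertical EOG is a sum of interpretable sources:

* **Blinks** — raised-cosine (Hann) pulses. Inter-blink intervals follow a
  Gamma(shape 2) renewal process rather than a Poisson process, because real
  blinks have a refractory period and near-zero intervals are
  physiologically impossible. We add the mean of the two adjacent blink
  half-durations as an explicit refractory gap and shrink the Gamma mean so
  the marginal interval mean is exactly `60/rate`; this keeps the configured
  rate unbiased *and* guarantees non-overlap by construction. Resting
  defaults: 16 blinks/min, 0.25 s, 130 µV — mid-range office values.
* **Stress modulation** — relative to rest, level 1 multiplies the blink
  rate by 1.4, duration by 1.2 and amplitude by 0.85; level 2 by 1.8, 1.4
  and 0.7. The directions follow the fatigue/workload literature (shorter
  inter-blink intervals, longer and smaller blinks under load); the
  magnitudes were chosen once to be detectable yet overlapping between
  classes, so classification is non-trivial.
* **Saccades** — a step process (12 events/min, ~25 µV) with a random 2-D
  gaze direction; the horizontal channel receives the cosine projection,
  the vertical the sine projection. These steps are the main source of
  false blink candidates, which is exactly what the template-matching stage
  must reject.
* **Drift and noise** — a 40 µV sinusoid with a 60 s period (electrode
  polarization drift) plus 5 µV white noise.
* **Motion artifacts** — 1 event/min: a 400 µV spike on the EOG with a
  coincident 1 g burst in the horizontal acceleration plane. Bursting the
  horizontal plane (not the gravity axis) guarantees the acceleration
  magnitude rises above baseline at every artifact, which is the property
  the artifact-rejection stage exploits. The accelerometer reports g with a
  1 g gravity baseline on z and 0.02 g axis noise, typical of eyewear IMUs.

Between-subject variability multiplies each subject's blink rate, duration
and amplitude by log-normal factors (sdlog 0.12, 0.08, 0.15), so LOSO folds
face genuinely shifted feature distributions.

What the generator does **not** emulate: pupil or smooth-pursuit dynamics,
eyelid closure asymmetry, electrode-contact degradation over time,
power-line interference, or realistic inter-task correlation of
self-reports. Passing tests on this cohort therefore demonstrate that the
pipeline recovers the structure it was designed to recover under controlled
conditions — not that the reported accuracies would transfer to human
recordings.

## Preprocessing

The EOG is band-passed with a 6th-order Butterworth at 0.25–7.5 Hz. We take
"6th order" to mean the overall filter order (three second-order sections);
the filter is applied forward–backward, which squares the magnitude
response and cancels phase, keeping detected blink apices aligned with
ground-truth times — an offline pipeline does not need causality. Inputs
are reflection-padded (about three periods of the low cut-off) so startup
transients do not leak into short test fixtures.

Acceleration axes are low-passed with an order-8 windowed-sinc (Hamming)
FIR at 10 Hz, normalized to exact unit DC gain because the 1 g gravity
baseline must pass unscaled. The artifact rule then thresholds the
magnitude of the *filtered* acceleration vector at mean + 3 sd (sample sd,
strict inequality — a constant magnitude masks nothing). EOG samples within
a ±0.5 s guard of any masked sample are replaced by linear interpolation
between the nearest clean samples: interpolation rather than deletion
preserves the uniform time base that fixed-length windows require, and the
0.5 s guard covers a blink-scale transient around the spike apex.

## Blink detection

Candidates are local maxima of the cleaned vertical EOG with topographic
prominence at least 3× a robust (MAD) noise-sd estimate, thinned to a
0.2 s minimum separation (taller peak wins — a physiological refractory
bound). Each candidate is scored against a unit-amplitude Hann template of
0.3 s: the template is scaled onto the apex-centred excerpt by least
squares, the event amplitude is that scale, and the score is
`rmse_norm = RMSE / amplitude`, which is invariant to signal rescaling.
Event duration is the template duration rescaled to the excerpt's measured
half-amplitude width (a Hann pulse's half-amplitude width is half its
duration). Acceptance is adaptive per session: events pass when
`rmse_norm` is at or below the Tukey upper fence (q75 + 1.5 IQR) of the
session's score distribution, capped at an absolute 0.5 so that a
uniformly poor candidate set is not accepted wholesale. On noise-free
synthetic sessions recovery is exact; with default noise the detector holds
F1 ≥ 0.9, with residual errors dominated by saccade steps that mimic small
blinks and by blinks corrupted by artifact interpolation.

## Features, labels and selection

Each retained 3 s window (150 samples) yields nine features: blink
frequency; mean peak-to-peak vertical amplitude across in-window blinks;
population variance of the vertical channel; covariance between the
vertical and the total signal; sd of in-window blink amplitudes; RMS of the
total signal; vertical maximum; and the mean and sd of the total signal.
Three of these names admit several readings, and we fixed conventions once:
the "total" EOG signal is the element-wise sum of vertical and horizontal
channels (the simplest composite using both components); the covariance
feature is cov(vertical, total) within the window; the RMS feature is taken
about zero, since the band-passed signal is already zero-mean. All
variances use the population (divide-by-n) convention so oracle tests have
a single closed form. Blink-dependent features default to 0 in blink-free
windows, keeping the matrix dense. Windows that cross a segment boundary
are dropped before labeling — a window spanning rest and task has no single
true label — which is why 12 × 882 windows shrink to roughly 10,400 labelled
rows.

Labels derive from the per-task Likert ratings: rest is `no_stress` in both
schemes; tasks are `stress` (two-class) when the rating is ≥ 2, and
`no_stress` / `stress1` / `stress2` (three-class) for ratings 0–1 / 2–3 / 4.
The thresholds are this package's convention; the emulated study never
printed its mapping.

Feature selection is an L1-penalized logistic (or multinomial) regression on
the z-scored training rows. When no penalty is supplied, it is chosen by
10-fold cross-validation on misclassification error, taking `lambda.1se` —
the sparsest model within one standard error of the best. Selection is
refitted inside every training fold, never on the full data set, to avoid
leakage; the standardization parameters are likewise fitted on training
rows only.

## Classifiers

Five reference classifiers are exposed behind one `model_spec()` /
`fit_stress_model()` / `predict()` surface, with shipped defaults equal to
the tuned optima of the emulated study (two-class / three-class):

| model | engine | defaults |
|---|---|---|
| RF | `ranger` | 8 / 6 trees, depth 12 / 14, Gini |
| LR | `glmnet` (ridge) | C = 0.05 / 0.03, λ = 1/(C·n) |
| SVM | `e1071::svm` | linear kernel, C = 0.1 / 0.5, one-vs-one |
| DT | `rpart` | depth 15 / 20, Gini, cp = 0 |
| KNN | built-in | k = 7 / 9, Euclidean, distance weights |

The harness — not the classifier internals — is the contribution, so
standard engines are used wherever one exists. Distance-weighted KNN is the
exception (no installed engine offers distance weighting), implemented
directly: weights 1/d, exact feature matches dominate with infinite weight,
remaining ties break to the first class in the model's class ordering. The
`max_iter` caps recorded for LR and SVM are solver-specific settings of a
different optimizer family; they are kept in the spec for completeness but
have no equivalent in the IRLS/libsvm fits and are not consumed.
`grid_search()` tunes any of these by validation accuracy on a stratified
10% inner split of the training rows, ties to the earliest grid row.

## Evaluation

`metrics_from_confusion()` computes accuracy plus one-vs-rest precision,
recall, F1 (`2TP/(2TP+FP+FN)`) and specificity per class, macro-averaged
for the summary — macro is the convention that also yields per-class
tables, and it is invariant under class relabeling. Zero-denominator cells
report 0 with a flag rather than NaN.

`evaluate_kfold()` partitions windows into stratified folds with a fixed
seed; every window is tested exactly once, and any grid search or Lasso
refit sees only that fold's training rows. `evaluate_loso()` makes one fold
per subject and audits, programmatically, that (a) train and test subject
ids are disjoint in every fold and (b) no identical feature row appears
under two subject ids — the second check catches the subtler leakage of
duplicated windows smuggled in under a new id. `per_task_accuracy()`
restricts the pooled test predictions to one task plus all rest windows,
measuring how separable each task is from baseline under the global model.

On the default cohort the two-class majority baseline is ~0.54 and all five
classifiers clear it by well over ten accuracy points under 10-fold CV,
with RF leading — the same ordering the emulated study reports, though the
absolute numbers are properties of the synthetic effect sizes, not of any
human data.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full default study —
12 subjects × 884 s at 50 Hz (≈ 530k samples, ~10.4k labelled windows) —
for the end-to-end claims, and short 140 s sessions for unit-level checks.
Monte-Carlo contracts (renewal-process mean, Lasso support recovery, null-
label chance level) use 50–1000 replicates at small n with fixed seeds and
3σ tolerances. Other numerical conventions: reflection padding before
filtering; strict inequality at the artifact threshold; interpolated spans
never leave the interval spanned by their boundary samples; candidate
apices closer than half a template to the signal edge are dropped; a Lasso
mask that empties (all coefficients zero) falls back to all usable features
so a classifier can still be fitted.

## Known limitations

* The template is a single fixed-width Hann pulse; real blink morphology
  varies with eyelid dynamics, and a learned template could score better.
* The adaptive acceptance fence assumes most candidates are blinks; on a
  signal dominated by non-blink transients the fence degrades toward the
  absolute cap.
* Self-report ratings are deterministic per task in the generator, so label
  noise — a major issue in real affective data — is not represented.
* Accuracies on synthetic cohorts depend directly on the configured effect
  sizes and must not be read as estimates for human data.
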