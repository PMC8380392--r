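---
title: "Methods: quantifying vestibular compensation with vestcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying vestibular compensation with vestcomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vestcomp)
options(vestcomp.verbose = FALSE)
```

This vignette is the package's own account of its methods: the
measurement models, the conventions adopted where the field's practice
leaves choices open, the synthetic-data model used to validate the chain,
and the limits of what those validations show.

## Coordinate conventions and units

All modules share one frame: x is the antero-posterior axis (positive
toward the head), y the lateral axis (positive toward the animal's
right). A positive lateral barycenter position or laterality index is a
rightward shift; body torsion is positive for a leftward
(counter-clockwise from above) bend. Units are grams, centimeters,
seconds and degrees throughout. Statokinesigrams are plotted with the
antero-posterior axis on the abscissa and the lateral axis on the
ordinate.

## Posturography

**Barycenter.** For each dynamic weight-bearing (DWB) frame the
barycenter is the paw-force-weighted mean position of the four paws. It
is undefined when the total paw force is zero (an error, never silently
zero), always lies in the convex hull of the paw positions, and reduces
to the centroid under equal loading.

**Stance epochs.** Posturographic quantities are computed only while the
animal is static and on four paws. The device does not mark those
periods, so detection is rule-based with three thresholds, all
config-overridable (`vc_config()`), defaults chosen as conventions:

* `min_paw_force` = 5 g — a paw is "loaded" above typical sensor noise;
* `min_duration` = 0.2 s — at least two frames at 10 Hz, so a
  single-frame touch never forms an epoch (durations are compared with a
  1 ns tolerance so an exactly-threshold epoch is kept regardless of
  binary float representation of timestamps);
* `max_barycenter_speed` = 2 cm/s — the static criterion; a faster
  barycenter step splits the run.

The representative frame of an epoch is the plain average of its member
frames, appropriate for the uniform sampling of DWB exports; epoch
duration is `end − start` plus one median sampling interval so that an
unbroken recording reports its nominal length.

**Dispersion statistics.** "Barycenter inertia" is implemented as the
duration-weighted mean squared Euclidean distance of the statokinesigram
points from their duration-weighted mean — the trace of the weighted
covariance. This is the simplest rotation- and translation-invariant
dispersion; the maximum lateral deviation is `max(Bary) − min(Bary)`.
Both are reported as ratios to the animal's pre-operative value; the
lateral position and the abdomen load are baseline-subtracted instead.
These normalization conventions are fixed per metric and recorded in the
tidy output's `normalization` column. A missing pre-operative baseline
yields a missing value with a warning — never an imputation. A
degenerate baseline (zero inertia or zero lateral span, possible when a
recording contains a single stance epoch) is an error at the function
level and a missing value in the pipeline.

**Circling.** Lap counting uses the unwrapped cumulative heading of the
body center, restricted to contiguous stretches where the instantaneous
speed stays at or above `min_speed` (default 5 cm/s, a convention; the
field says only "fast laps"). A lap is counted each time the cumulative
heading advances 360° beyond its running minimum (for left laps), so
partial laps and slow rotations never count, and the left count on a
trajectory equals the right count on its mirror image.

## Open-field kinematics

Distance, velocity and acceleration come from finite differences of the
center track after an optional boxcar smoother (default 0.5 s; raw
differencing of 25–30 Hz tracking noise would inflate acceleration).
Mean acceleration is the mean *magnitude* of the acceleration vector —
the scalar that is well-defined for a meandering path. Mean body torsion
is the signed angle between the tail→center and center→nose vectors
(the "bend" of the animal), averaged over samples; coincident or masked
samples are skipped with a warning. Locomotor metrics normalize as
post/baseline ratios, torsion as a difference — matching how these
quantities are conventionally reported.

## Image quantification

**Support surface.** The area between the four paws on landing is the
shoelace area of the quadrilateral in perimeter order FL→FR→RR→RL,
averaged over the session's repeated trials (nominally 10) and divided by
the animal's pre-operative session mean, so baseline maps to exactly 1.

**Membrane fluorescence.** The background threshold is
`mean + 3·SD` of a user-selected region devoid of stained structures
(≥ 50 pixels enforced); the image is reduced by the threshold and
negative values discarded. Within each membrane ROI the reported value is
the mean of retained pixels at or above 80% of the ROI maximum. The
"top-band" rule deserves a note: the quantity is described in the
literature as averaging data "20% above the maximum", which read
literally is empty (no pixel exceeds the maximum); we implement the
band `[0.8·max, max]`, which keeps the average on the brightest,
membrane-proper pixels under one criterion for all images. Cells with no
suprathreshold pixel are flagged and excluded from the image mean with a
warning. Because the threshold tracks the background, adding a constant
to a whole image leaves results unchanged — asserted on synthetic images.

**Cell counts.** Counting uses a parameterized square counting frame
(the chamber area is configuration, never hard-coded behavior; the
conventional figure of 425.10 mm² is carried as a label — its unit is
odd for a microscopic frame, more plausibly µm²-scale, and nothing
numerical depends on it). Detection is background subtraction, a fixed
threshold (default image mean + 3 SD), connected components
(`EBImage::bwlabel`) with a minimum area, counted when the centroid falls
inside the frame. Real studies count manually; this detector is a
stand-in validated only on synthetic images with planted,
well-separated blobs, where it recovers the planted count exactly.
Colocalization is greedy one-to-one centroid matching within a radius
(default 3 µm). Survival is `100 × late / acute` mean counts; both the
per-animal-then-average and the group-mean routes are available because
published percentages are ambiguous between them.

## Statistics

**Normality.** The D'Agostino–Pearson omnibus statistic combines the
transformed skewness (D'Agostino 1970) and kurtosis (Anscombe–Glynn
1983) into `K² = Zs² + Zk²`, referred to χ²(2), with Q-Q coordinates
returned for the visual screen. It requires n ≥ 8 and rejects constant
samples.

**ANOVA.** `vc_anova()` fits either an independent two-factor ANOVA
(cellular designs, different animals per time point) or a split-plot
(1-between "group", 1-within "time") ANOVA for behavioral time courses,
via `aov()` with an `Error(animal)` stratum. The group effect is tested
against the between-subject error; time and group×time against the
within-subject error. No sphericity correction is applied by default —
matching the conventional reporting of this battery; the fitted strata
(mean squares and df) are exposed, so a corrected analysis can be
layered on. Incomplete within-subject series are dropped with a warning.

**Tukey comparisons.** The reported ratio is
`q = √2·|m₁ − m₂| / SE_diff` with `SE_diff = √(MSE·(1/n₁ + 1/n₂))`
(Tukey–Kramer when unbalanced) and p from the studentized-range
distribution (`ptukey`, numerical integration; cross-checked in the
tests against a 10⁶-draw Monte-Carlo oracle and against `TukeyHSD`).
This convention was fixed by recomputation against a published
comparison table: it reproduces all five worked rows to their printed
precision. The correction family defaults to *all group×time cell
means* — consistent with the large error degrees of freedom seen in
published tables of this battery — and is configurable to the
three-group family. For split-plot fits, group comparisons at a fixed
time pool the two error strata, `(MS_b + (T−1)·MS_w)/T`, with
Satterthwaite degrees of freedom.

## The synthetic cohort model

The generator encodes the study conditions the package is designed for:
three groups — sham (n = 21), lesion + placebo (n = 21), lesion +
treated (n = 19) — observed pre-operatively and at post-operative days
1, 2, 3, 7, 14, 21 and 30. A latent syndrome intensity

`s(t) = s∞ + (s0 − s∞)·exp(−λ·t)`,  `s(preop) = 0`, sham ≡ 0

drives every readout monotonically. Exponential decay is the simplest
family matching the described time course (acute syndrome over the first
three days, progressive compensation); the defaults are
`λ = 0.30/day, s0 = 0.90, s∞ = 0.10` for placebo and
`λ = 0.12/day, s0 = 0.95, s∞ = 0.22` for the treated group — slower
recovery and a higher residual plateau under treatment, consistent with
an anti-inflammatory treatment that delays compensation. A per-animal
random effect (SD 0.06) is added to `s` and truncated to [0, 1].

Behavioral links (all defaults are package conventions, tuned once so
that pipeline outputs land in the ranges reported for this battery —
e.g. support-surface ratios near 1.15 (placebo) vs 1.76 (treated) at
day 7, sham rearing near 50% — and not revisited): leftward weight
fraction 0.5 + 0.1·s; abdomen load 2 + 20·s g; rearing probability
0.5·(1 − 0.8·s); body sway and between-stance repositioning grow with
`s` (barycenter dispersion); torsion 13·s degrees with 8° sample noise;
speed suppressed by 0.7·s acutely with late hyperactivity in lesioned
groups; counter-clockwise circling bouts at rate 12·s per 10 min during
the acute days; support-surface area inflated by 1 + 1.4·s. Within-stance
sensor noise (2% force CV, 0.02 cm paw jitter) is set so a resting
animal's barycenter speed stays well under the 2 cm/s static criterion,
as in the real device. Fluorescence images carry constant-intensity
membrane rings on a N(10, 2²) background and well-separated Gaussian
nuclei; cellular count targets per group×day follow the magnitudes of
published marker tables.

Reproducibility: one master seed; per-record, per-component substreams
are drawn up front, so regenerating a subset of components never
perturbs the others, and the same config + seed is byte-identical.

**What the generator does not emulate** — and therefore what green tests
do *not* show about real data: biomechanically realistic force
waveforms, gait structure, wall-following/thigmotaxis, tracker artifacts
beyond simple dropouts, imaging point-spread functions or uneven
illumination, and any correlation structure between behavioral and
cellular readouts beyond their common dependence on `s`. Passing
parameter recovery shows the chain is self-consistent under the stated
model, not that exponential kinetics are the truth for any real cohort.

## Parameter recovery and problem sizes

`parameter_recovery_report()` fits `y = c0 + c1·e^(−λt)` (nonlinear
least squares, Levenberg–Marquardt, λ ≥ 0) to each lesioned group's mean
post-operative time course of a metric linearly linked to `s` — mean
body torsion by default — and summarizes bias and RMSE of λ across
replicate cohorts. With noise off, λ is recovered to < 1%; under the
default noise with 20 animals/group, λ RMSE is a few percent of truth.
The recovery study and the calibration checks run at deliberately chosen
sizes — 50 replicate cohorts of 20 animals/group with 60 s open-field
recordings at 10 Hz, 2000 null replicates for the ANOVA→Tukey
familywise error, 10⁶ draws for the studentized-range oracle, 1000
replicates for the normality screen — sizes at which the Monte-Carlo
standard errors are comfortably inside the decision bands.

## Numerical choices and degenerate inputs

* Barycenter with zero total force, statokinesigram with zero epochs,
  Tukey with non-positive error df, survival with zero acute count:
  errors with distinct messages.
* Stance-epoch durations compared with 1e-9 s tolerance (float-safe).
* `fit_syndrome_kinetics` starts from (last value, first-minus-last,
  λ = 0.2) and bounds λ to [0, 10]/day.
* Tracking dropouts are masked samples: excluded from differences and
  bend angles, never interpolated.
* The q ratio is reported to full precision; rounding only happens in
  print methods.

## Known limitations

Single counting frame (no stereology); no sphericity correction and no
mixed-model likelihood alternative; the circling counter needs actual
center translation (a rotation purely in place, below the speed gate, is
not a "fast lap"); the image detector is not meant for real micrographs
without retuning; `read_cohort()` expects the package's own exchange
layout rather than raw device exports — device dialects are handled for
force frames via the configurable column map.
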