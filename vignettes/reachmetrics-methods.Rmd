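---
title: "Methods: stereotypy, MEP and dosimetry analysis for skilled reaching under tDCS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stereotypy, MEP and dosimetry analysis for skilled reaching under tDCS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachmetrics)
```

`reachmetrics` analyses rodent single-pellet reaching experiments in which
weak transcranial direct current stimulation (tDCS) is applied concurrently
with daily training. Four measurement streams feed the pipeline: high-speed
(309 fps) markerless pose tracking of the reaching paw, EMG sweeps holding
motor-evoked potentials (MEPs), intracranial potentials on a four-contact
lattice used to calibrate the stimulation current, and the animal-by-day
table of reaching successes. This vignette explains the models and
procedures, the tunable parameters and their defaults, what the synthetic
generators emulate, and the numerical conventions chosen where more than
one was defensible.

## Trajectory stereotypy by template matching

A trial is a pose table: per-frame x/y/likelihood for five digits, the
wrist and the pellet, in image coordinates (origin top-left, y downward,
0-based frames). Traces are despiked with a running median
(`median_filter_track()`, default 5 samples = 15 ms at 309 fps; edges use
a shrinking window, so series length is preserved). Left-pawed animals'
trials are mirrored (`mirror_if_left()`, `x -> width - 1 - x`) so a single
template convention serves all animals; paw preference itself follows the
shaping rule of `paw_preference()` — the paw used at least 6 of the first
10 shaping reaches, with a 5–5 split returned as `undetermined` so the
experimenter extends shaping rather than guessing.

The canonical grab is a **template**: a 50-sample (150 ms) by
10-coordinate matrix (five digits × x,y; the pellet is tracked for
bookkeeping but does not enter the statistic), built by element-wise
averaging of three grab windows, one from each of three trials of the
session (`build_template()`). Because no rule for choosing those three
grabs is canonical, `session_template()` implements a documented
bootstrap: a seed template is averaged from the windows at each trial's
peak digit speed, slid along the first trials, and the best-scoring grab
from each of the first three trials with a detection forms the final
average. The seed may lock onto a time-shifted copy of the underlying
movement; this is harmless because every trial is scored against the same
template and the correlation statistic is shift-consistent.

`sliding_correlation()` computes, at every alignment where the full
window fits, the Pearson correlation between the 50-sample trial window
and the template, separately per coordinate, averaged across the 10
coordinates. Three conventions matter:

* **Normalisation.** The statistic is the Pearson correlation
  coefficient per coordinate (mean- and variance-normalised per window),
  not a raw sliding dot product. This makes the score translation- and
  scale-invariant and bounds it in [-1, 1], which is what one wants from
  a stereotypy measure. A zero-variance window or template coordinate
  contributes 0 (logged), never NaN.
* **Alignment.** Windows are labelled by their center frame
  (`center -> sample 25 of 50`); a `"start"` convention is available.
* **Edges.** Alignments whose window would overrun the trial are
  excluded, not zero-padded, so the "last peak" can never be an edge
  artifact.

`detect_grabs()` takes local maxima of the averaged correlation above
`min_score` (default 0.3), kept greedily in descending score order with a
minimum separation (default 50 samples, one template length). Both
thresholds are exposed because no canonical values exist; the defaults are
deliberately permissive — separation below one template length would let a
single grab be counted twice, and scores below 0.3 are indistinguishable
from background matches of the resting posture. The last surviving peak is
the **final grab**, which contains the successful reach when there is one,
and the correlation at that peak is the trial's **stereotypy score**.
Trials with no detected grab yield a missing score and are excluded from
statistics with a logged count. The implementation (running sums plus
one-sided convolution) is checked in the test suite against a brute-force
`cor()` oracle at every offset to 1e-10.

## MEP quantification

Each sweep is EMG in mV sampled at 10 kHz with a recorded stimulation
onset. The per-trial statistic is the mean of the rectified signal in a
**half-open window 10–30 ms after the first pulse** (inclusive start;
sample *i* at time *(i−1)/fs* is included when `t0 <= t < t1`). Sweeps
are assumed artifact-truncated upstream; an optional blanking window
(e.g. 0–8 ms) is available but off by default. The condition-level
amplitude is the **median across the 20 trials** (mean of the middle two
for even counts) — robust to occasional contaminated trials — and all
statistics use its natural logarithm, so differences read as amplitude
ratios and the base cancels.

The **motor threshold** is the smallest tested current at which at least
90 % of trials exceed the 0.05 mV noise floor; with 20 trials the 90 % is
implemented as the ceiling rule ≥ 18/20. `recruitment_curve()` orders
condition amplitudes over the standard 90/100/120/140/200 % intensity
ladder, flagging missing intensities rather than interpolating.
`contra_ipsi_log_contrast()` forms `log(contra) − log(ipsi)` per animal ×
paw, cancelling per-animal EMG-strength differences because both sides
share the recording electrode. Exclusion criteria such as "unreliable
threshold" are not operationalisable from the data alone; the pipeline
flags (zero medians, missing intensities) but never auto-excludes.

## Electric-field dosimetry

Potentials are recorded at four contacts on a 1 mm square planar lattice
during sinusoidal transcranial stimulation. Per channel, the component at
the stimulation frequency is fitted by least squares (sine + cosine +
offset over an integer number of cycles; `sinusoid_amplitude()`). The
2D field is the finite difference of the potential over the lattice:
each component is the mean of the two parallel pair differences divided
by the 1 mm spacing, with sign convention **E = −∇V**. For a uniform
field this is exact, and the generator constructs exactly that, so the
round trip is tested to 1e-10 at zero noise. Because the absolute phase
of the carrier is unobservable, signed components are reported along the
dominant phase direction (oriented so the dominant component is
positive); the magnitude is phase-insensitive
(`sqrt(|dx|² + |dy|²)/1 mm`) and is the quantity used downstream.

The **gain** is the slope of magnitude versus current **through the
origin** (zero current gives zero field); ordinary residuals are reported
as a linearity diagnostic. Gains are reported per frequency — recording
chains are typically calibrated for unit gain at 1000 Hz, so the
calibration gain is taken at the user's chosen frequency rather than
pooled. `calibrate_current(target, gain)` then inverts the gain,
e.g. a 2 V/m target at a montage gain of 0.0141 (V/m)/µA requires
≈ 142 µA. Occasional gross measurement outliers are flagged by comparing
residuals against a **robust** reference slope (the median of per-point
magnitude/current ratios) at 3× the median absolute residual; measuring
residuals against the least-squares line would let a single large outlier
drag the line toward itself and escape its own flag. Flagged points are
excluded only on explicit request. Gain is always a measured input:
the package never hard-codes a published gain value, since printed
montage gains differ by electrode holder and calibration frequency.

## Learning-curve statistics

All longitudinal analyses are linear mixed models fitted by REML
(`lme4`/`lmerTest`) with **day coded as natural log(day), day 1 = 0**, to
capture the saturating learning curve, and a **random intercept per
animal**. A random log-day slope is available behind `random_slope =
TRUE` for likelihood-ratio comparison, but the primary models use the
intercept-only structure. Cumulative stimulation effects appear as the
group × log(day) interaction. Missing days (e.g. an animal losing its
headcap late in training) are handled by likelihood, not imputation.
Satterthwaite approximations give the t/F denominator degrees of freedom;
other software may report slightly different df for the same data, which
is why validation is by synthetic parameter recovery rather than df
matching. Non-convergence and singular fits are flagged on the returned
object (`converged`, `singular`), never silently repaired. No
multiple-comparison correction is applied, and every printed fit says so.

Model shapes: `fit_success_model()` (successes), `fit_rate_model()`
(successes/attempts as a Gaussian response — mirroring the analysis
convention this pipeline reproduces, not a binomial model; the mismatch
matters mainly near rate 0 or 1), `fit_stereotypy_model()` (per-trial
scores, with paw-preference and outcome subsetting, since left- and
right-pawed animals behave differently around the reach), and
`fit_mep_model()` (side, contra−ipsi log-difference with tDCS × training,
and amplitude-versus-success shapes; "success" is taken as final-day
successful reaches, an interpretation the caller can override by
supplying any `successes` column).

## Synthetic data: what it emulates and what it does not

Every input kind has a generator with known ground truth, so each stage
has a quantitative acceptance surface without animal data.

* **Pose trials** (`sim_pose_trials()`): each trial embeds a configurable
  number of copies of a canonical grab waveform (a smooth
  reach-advance-close-retract arc returning exactly to the resting
  posture) at recorded centers (≥ 60-frame separation, 25-frame margins),
  distorted by a smooth perturbation scaled by `1 − stereotypy_level`
  (default jitter SD 6 px), a mild random time warp (SD 2 %), plus white
  measurement noise (SD 1 px, comparable to a tracking model's test
  error). The defaults give high absolute correlation scores; the tested
  property is the strict ordering of mean scores in `stereotypy_level`,
  not their absolute level. Real trials differ: background behaviour is
  not stationary posture, distortions are not Gaussian, and tracking
  failures produce low-likelihood segments rather than uniform noise — so
  passing tests demonstrate correctness of the scoring machinery, not
  field performance of the thresholds.
* **Learning tables** (`sim_learning_table()`): Gaussian draws around the
  exact linear-in-log-day predictor with per-animal intercepts, rounded
  and floored at zero by default. The Gaussian generative model matches
  the fitted model by design; true success counts are discrete and
  right-skewed early in training, a mismatch the rounding only partially
  imitates. Exact-recovery checks therefore use the un-rounded response
  (`integer_counts = FALSE`); simulations at cohort scale (24 animals ×
  10 days, intercept SD 2, residual SD 3 successes) keep the rounded
  counts. Attempts are successes plus Poisson misses (mean 25), and paw
  preference is drawn with P(right) = 13/24, the proportion of the cohort
  the defaults emulate.
* **MEP sweeps** (`sim_mep_sweeps()`): Gaussian baseline noise (SD
  0.02 mV) plus an oscillatory burst (150 Hz carrier, squared-sine
  envelope) confined to 12–27 ms after the pulse, inside the analysis
  window; burst peak follows a logistic recruitment curve of intensity
  (midpoint 110 %, slope 1.5 per 10 %, maximum 1.5 mV) with lognormal
  trial-to-trial variability (CV 0.25). Real MEPs have multiphasic,
  animal-specific shapes; only the window-mean/median/threshold
  reductions are validated, not waveform realism.
* **Field recordings** (`sim_field_recordings()`): potentials are the
  exact dot product of a uniform sinusoidal field with the lattice
  coordinates plus white noise (SD 5 µV), i.e. the uniform-field
  assumption holds by construction. Real tissue adds impedance phase
  shifts and non-uniformity that this generator deliberately omits — the
  estimator's finite-difference step is exactly correct only for uniform
  fields, and that is the regime being tested.

Determinism: every generator draws from per-unit sub-streams derived from
one integer seed, so a given trial/animal/sweep is bit-reproducible and
unchanged when the collection grows.

## Numerical choices and degenerate inputs

* Median filter edge policy: shrinking window (configurable by choosing
  `window = 1` to disable); even windows rejected.
* Correlation ties in peak detection break toward the earlier frame via
  the `>=`/`>` neighbour rule; plateau maxima yield a single event.
* `detect_grabs()` on a monotone series returns nothing (no interior
  maximum), and its event count is bounded by `floor(len/min_sep) + 1`.
* Half-open windows everywhere ([10, 30) ms; template frames
  [c−25, c+25)) so adjacent windows never double-count a sample.
* Zero medians make the log amplitude `NA` with a flag rather than
  `-Inf`; zero-attempt sessions are dropped from the rate model with a
  message; a 5–5 paw split is `undetermined`, not an arbitrary side.
* MAD-degenerate outlier sets (all residuals equal) flag nothing because
  the rule uses a strict inequality.

## Problem sizes used in validation

The packaged tests and the acceptance script run entirely on synthetic
cohorts sized to the experimental design they emulate: 100 trials × 3
grabs for detection (≥ 95 % recovery within ±3 frames), 20 random
400-frame trials for the correlation oracle, 100 trials per stereotypy
level, 20 trials × 5 intensities for MEP, 3 currents × 3 frequencies for
dosimetry with 100 Monte-Carlo gain recoveries (within 2 %), and 24
animals × 10 days for the mixed models — 200 null replicates for the
size of the interaction test (binomial 95 % band around 5 %) and 100
replicates for CI coverage (≥ 93 expected). Published headline statistics
from any particular animal cohort are functions of data that are not
distributed with this package; the validation targets are therefore the
properties above, all recomputed at run time.

## Known limitations

Stereotypy uses fixed-length windows: it has no dynamic time warping, so
a uniformly slower grab scores lower even if spatially identical (the
generator's small time-warp SD reflects this sensitivity). The rate model
treats a bounded ratio as Gaussian. The dosimetry model assumes a uniform
field over the 1 mm lattice and estimates no DC gain (electrode
polarisation makes 0 Hz measurements a different problem). The
paw-preference rule is only defined for the first 10 shaping reaches.
None of the fits correct for multiple comparisons.
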