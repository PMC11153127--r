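---
title: "Methods: kinematic phenotyping, photometry and dose-response analysis"
author: "opiometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinematic phenotyping, photometry and dose-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opiometrics)
```

`opiometrics` implements the quantitative analysis chain used to phenotype
opioid withdrawal and reinforcement behaviour in mice: post-processing of
markerless pose-estimation output, per-frame kinematic variables, detection
of withdrawal jumps and immobility, place-preference scores,
fibre-photometry ΔF/F analysis, feature-based time-series classification
with a permutation null, and four-parameter logistic dose–response fits.
A fully seeded synthetic-data generator stands in for raw videos and
recordings, so every stage can be validated against ground truth.

## Pose post-processing

Pose tables carry 15 tracked points — 11 on the animal (nose, ears,
shoulders, body centre, hips, and the tail base/middle/end) and the four
arena corners — each with per-frame x/y (pixels, image convention: origin
top-left, y down) and a tracking likelihood in [0, 1].

`correct_coordinates()` replaces, per point, frames that are unreliable:

* **Low confidence** — likelihood strictly below 0.05.
* **Position outliers** — more than 5 px outside the corner bounding box.
* **Displacement glitches** — the steps into *and* out of a frame both
  exceed 6 robust SDs (1.4826 × MAD) of that point's per-frame
  displacement, *and* the point returns (net displacement across the frame
  below the same threshold). The return condition matters: distal points
  such as the tail end genuinely sweep tens of pixels per frame during
  fast turns, and flagging sustained fast motion would interpolate real
  behaviour away.

Replacements come from a natural cubic interpolation over the remaining
valid frames; runs at the sequence edges take the nearest valid value
rather than extrapolating. Likelihoods are never altered, so event
detection downstream always sees the raw confidence. `smooth_coordinates()`
then applies a centred moving average of width 5 frames (shrinking at the
edges), and `calibrate_arena()` converts pixels to centimetres using the
median corner-to-corner side of the 20 cm square arena.

**Ordering.** Jump detection relies on frames where tracking collapses and
the animal moves explosively — exactly the frames an outlier filter would
"fix". The pipeline therefore derives *candidate jump windows* from the
raw confidences first (`candidate_jump_frames()`: runs of mean animal
likelihood below 0.5, padded by 0.25 s) and exempts them from outlier
replacement. Low-confidence single-point dropouts inside those windows are
still repaired.

## Kinematic variables

`compute_kinematics()` derives 14 relative variables plus the jump
likelihood (`KINEMATIC_VARIABLES`). Conventions the source data do not
dictate were fixed as follows:

* Angles sit at the natural joints of the labelled skeleton: body–tail at
  the tail base (shoulders-mid → tail base → tail middle), mid-tail at the
  tail middle, head–body at the shoulders midpoint (nose → shoulders-mid →
  hips-mid). All interior angles lie in [0, 180]°.
* Body rotation is the signed angle of the shoulders-to-hips axis against
  the image vertical, in [−180, 180)°. For an axis-aligned arena the image
  vertical and the arena wall coincide, so the choice is immaterial there.
* Torsion is the left shoulder–hip distance over the right; a symmetric
  posture gives exactly 1.
* Speed is the body-centre displacement between consecutive frames times
  the frame rate.
* The jump likelihood is one minus the mean likelihood of the 11 animal
  points. The static corners are excluded; averaging them in would dilute
  the whole-body dropout that signals a jump.
* **Rearing proxy.** Top-view data do not observe height, so rearing is
  inferred from its 2-D signature: the spine foreshortens. A frame is
  flagged when body extension stays below 60 % of its session median for
  at least 0.25 s while speed is below 2 cm/s. This is a stated convention
  of this package, exposed as parameters, not a measured ground truth.

## Behavioural events

**Jumps.** A maximal run of frames with tracking confidence below 0.50
(runs closer than 0.125 s merged, runs under 2 frames dropped) is a jump
iff the speed within ±0.25 s of the run exceeds 10 cm/s. The two
thresholds are the standard ones for this assay; the window and merge gap
are configuration, chosen to span one jump's flight time at 40 fps.

**Immobility.** Immobility is scored on `immobility_speed()` — the
per-frame displacement of the *mean of the 11 animal points*, which
reduces independent tracking jitter by roughly √11 without any temporal
smoothing, keeping bout edges sharp to about one frame. The default
threshold is 4 cm/s with a 2 s minimum bout. The threshold sits where it
does because per-frame centroid displacement at 40 fps has an irreducible
noise floor: with 1.5 px jitter per point, the 11-point mean still shows
~1.3 cm/s of apparent speed at rest, so thresholds of 1–2 cm/s classify
pure noise as movement. 4 cm/s is comfortably above that floor and far
below slow locomotion (~8 cm/s). Isolated above-threshold interruptions
shorter than 0.25 s (single-frame glitches, twitches) do not break a bout;
detected jump windows always do (`exclude` argument), since a jump is
movement by definition.

**Distance travelled** integrates the per-frame centroid displacements in
metres, excluding detected jump windows where tracking is invalid.

**Preference scores.** CPP and RTPA scores are the time in the target
compartment divided by the time in both choice compartments; corridor time
never enters the denominator. Complementarity
(`score(target) + score(other) = 1`) is exact.

## Fibre photometry

The 405 nm isosbestic channel is the motion-and-bleaching control. Over
the baseline window (default the first 5 min) the package fits the least
squares line predicting the 470 nm signal from the 405 nm signal and
applies it to the whole recording; ΔF/F is then
`(f470 − fitted405) / fitted405`, with no further detrending. Binning
(default 10 s) keeps a flagged trailing partial bin.

**Transients** are strict local maxima of ΔF/F whose *topographic
prominence* — height above the higher of the two reference saddles toward
the nearest higher sample — exceeds 2 standard deviations of the baseline
ΔF/F. The prominence routine is implemented in this package and tested
against a brute-force oracle. Peaks closer than 0.5 s are resolved in
favour of the more prominent one; the separation parameter is exposed.
A practical note: a 2 SD prominence rule is only selective because real
baselines contain spontaneous transients that inflate the baseline SD well
above the instrument-noise floor. On data whose baseline is pure
instrument noise the rule would flag noise excursions — this is a property
of the rule, not of the implementation, and the synthetic generator
therefore models spontaneous activity throughout the recording.

**AUC** is the trapezoidal integral at native sampling (exact to O(Δt²)
for smooth signals); post-injection windows default to 20 min for calcium
sessions and 40 min for dopamine-sensor sessions, and no baseline mean is
subtracted since ΔF/F is already baseline-referenced. To compare animals
with different sensor expression, `normalize_auc()` references the
drug-evoked AUC to the apomorphine-evoked AUC *and returns both
orientations explicitly labelled* — conventions differ on which ratio is
printed, and emitting both avoids a silent choice. Peri-event averages
drop (and count) events whose window is clipped by the recording edges.

## Time-series classification

Each animal contributes one time series per kinematic variable; one
classifier is trained per variable (a joint mode over all variables is
available, but per-variable is the default). Series are summarised by a
fixed, versioned catalogue of 41 features (`TS_CATALOGUE_VERSION`):
moments, quantiles, autocorrelations at lags 1/2/5/10/20, crossing rates,
spectral band powers and entropies, permutation entropy, split-half
stationarity, run lengths, outlier fractions, difference statistics,
linear trend and Hjorth parameters. Degenerate inputs follow fixed
conventions (a constant series has zero variance and zero
autocorrelation/entropy/crossing features). This reduced catalogue
deliberately replaces exhaustive feature libraries: the downstream
inference — separability of groups with a permutation control — does not
depend on catalogue breadth.

Classification is a linear support-vector machine at fixed cost 1 (no
tuning), evaluated by stratified k-fold cross-validation (5 × 5 by
default). Standardisation uses training-fold statistics only; constant
columns are dropped and non-finite entries imputed with the training
median. Each fold yields a sensitivity and specificity and the balanced
accuracy is their mean, averaged over folds and repeats. Fold assignment
derives from a canonical (lexicographic) row ordering before the seeded
deal, so jointly permuting rows of the dataset cannot change the partition
— an invariance the tests assert exactly.

Significance uses label shuffling: the full cross-validation is rerun on
`n_shuffles` shuffled copies (default 1000) and
`p = (1 + #[null ≥ observed]) / (n_shuffles + 1)`, the add-one estimator
that cannot return zero.

## Dose–response

The occlusion dose–response uses the log-dose four-parameter logistic with
a signed Hill slope,

$$y = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
{1 + 10^{(\log_{10}\mathrm{IC}_{50} - \log_{10} d)\,h}},$$

so a response that falls with dose has \(h < 0\) and runs from `top` at
low doses to `bottom` at high doses. Fitting is nonlinear least squares on
log dose (Levenberg–Marquardt), initialised from the data (top = mean at
the lowest dose, bottom = mean at the highest, IC50 = geometric mid-dose,
hill = −1) with five jittered restarts, lowest residual sum of squares
winning. Per-subject responses are fit unweighted (per-mouse mode is the
default; a group-mean mode exists). Zero-dose (saline) rows are excluded
from the fit, where log dose is undefined; for plotting they may be mapped
one decade below the smallest tested dose. Constant responses yield a
flagged failure rather than a spurious fit. `occlusion_curve()` normalises
each subject's rates to its own saline baseline before summarising.

## The synthetic-data generator

`gen_pose_session()` emulates a 40 fps, 640×480 px top-view recording of a
20 cm arena. Behaviour is a semi-Markov program with gamma dwell times
over locomotion (8 cm/s), immobility, and rearing, with a 0.5 s minimum
dwell; an `effect_size` parameter scales the immobility dwell by
`exp(effect_size)` and locomotion by its inverse, so `effect_size = 0` is
an exact null. Withdrawal jumps arrive as a Poisson process and are
implemented as 0.3 s ballistic out-and-back displacements (60 cm/s peak)
aimed at the arena interior, during which all animal-point likelihoods
drop into [0.05, 0.45]. The 11-point rigid body template (spine contracted
to 45 % during rears) rides on a heading that only turns while the animal
moves and steers smoothly away from walls; walls clamp body points that
would poke beyond them, as a real wall does. Tracking imperfections are
isotropic Gaussian jitter (1.5 px), sporadic per-point dropouts (2 % of
point-frames: likelihood below 0.05 plus a 20–60 px position spike), and
near-unity likelihoods otherwise. Ground truth lists every jump and every
centroid-quiescent bout — quiescence, not the rearing/immobile distinction,
is the correct reference for a centroid-speed detector, and a rearing
mouse translates its top-view centroid at well under any plausible
threshold.

`gen_photometry_session()` emulates a 20 Hz two-channel recording:
a shared exponential bleaching drift (5 a.u. on a 100 a.u. baseline, τ =
600 s), a shared Ornstein–Uhlenbeck motion artifact (SD 1 a.u., τ = 2 s)
— correlated nuisance the isosbestic regression must remove — plus, on the
470 nm channel only, double-exponential transients (rise 0.1 s, decay
0.5 s, amplitude 5 % ΔF/F) at 5 events/min *throughout the recording*, an
optional slow injection response, and 0.1 a.u. white noise per channel.
Spontaneous baseline activity is essential realism, not decoration: it
sets the baseline SD that the 2 SD prominence rule thresholds against.

`gen_dose_response()` draws per-subject responses on the 4PL with
multiplicative Gaussian noise truncated at zero;
`gen_preference_session()` builds three-compartment occupancy tracks whose
dwell times match the request to within one frame.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: pose-estimator systematic biases (identity
swaps, lighting- or occlusion-dependent error correlated across points),
soft-body kinematics beyond the rigid template, wall-supported rearing
postures, photometry bleaching nonlinearity and hemodynamic artifacts,
sensor kinetics varying with indicator expression, and any real biological
group difference. Validation on these data certifies the *pipeline
mechanics* (thresholds, estimators, calibration of the permutation test),
not biological effect sizes.

## Validation problem sizes

The shipped validation suite (and `scripts/acceptance.R`) uses sizes
chosen to give stable estimates on a single CPU: 200 replicate
dose–response experiments per task (9 or 7 subjects, 10 % CV); 20
ten-minute pose sessions (~370 true jumps) for detector scoring; 20
25-minute photometry sessions (~2,500 true transients); 200 null
classification datasets of 20 animals per group (30 s sessions, speed as
the classified variable, 200 shuffles, one CV repeat) for permutation
calibration; one 40-animal strong-effect dataset (300 s sessions,
`effect_size = 3`, 200 shuffles, 5 repeats) for the saturation check.

## Known limitations

* The rearing proxy and the immobility threshold are conventions; both are
  parameters, and sessions with very different body scales or frame rates
  will need them revisited.
* The immobility detector's single-frame edge accuracy presumes sharp
  stop/start transitions; gradual decelerations blur the boundary by the
  smoothing width.
* The transient detector inherits the 2 SD prominence rule's dependence on
  a representative baseline: a baseline window without spontaneous
  activity makes it permissive.
* `fit_logistic4` assumes a monotone dose–response; biphasic data will fit
  poorly and should be caught by inspecting residuals.
* The classification null calibration holds for the shipped catalogue and
  CV scheme; adding tuned hyperparameters inside the CV would require
  nesting the permutation accordingly.
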