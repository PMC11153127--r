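# opiometrics

Quantitative analysis of opioid withdrawal and reinforcement behaviour in
mice, for behavioural neuroscientists working with markerless pose
estimation, fibre photometry and operant dose–response data.

The package implements, as tested reusable components:

* **Pose post-processing** — DLC-style table I/O, replacement of
  low-confidence (< 0.05) and outlier coordinates by natural cubic
  interpolation, width-5 moving-average smoothing, and arena calibration
  from the tracked corners of the 20 cm chamber.
* **Kinematics** — 14 per-frame relative variables (body extension,
  shoulder/hip distances, tail measures, three joint angles, body
  rotation, distance to box centre, torsion, speed, rearing) plus a 15th
  variable, the jump likelihood *P*(jump) ≈ 1 − tracking confidence.
* **Withdrawal events** — jump detection (confidence < 0.50 with speed
  > 10 cm/s around the loss of tracking), immobility bouts (≥ 2 s below a
  speed threshold), distance travelled in metres, and CPP/RTPA preference
  scores `t_target / (t_target + t_other)`.
* **Fibre photometry** — baseline regression of the 405 nm isosbestic
  control onto the 470 nm signal,
  ΔF/F = (F470 − fitted405) / fitted405, 10-s binning, transient
  detection by topographic prominence > 2 baseline SDs, trapezoidal AUC,
  apomorphine normalization, and peri-event averaging.
* **Time-series classification** — a 41-feature catalogue per series, a
  linear SVM under 5 × 5 stratified cross-validation scored by balanced
  accuracy = (sensitivity + specificity)/2, and a label-shuffling
  permutation test, p = (1 + #[null ≥ observed]) / (n\_shuffles + 1).
* **Dose–response** — log-dose four-parameter logistic
  `y = bottom + (top − bottom) / (1 + 10^((log10 IC50 − log10 d)·h))`
  with a signed Hill slope, multi-start Levenberg–Marquardt fitting, and
  saline-baseline normalization of occlusion rates.
* **Synthetic data** — seeded generators for pose sessions (semi-Markov
  behaviour, ballistic jumps with likelihood dropout, tracking jitter),
  two-channel photometry (shared drift and motion artifact, spontaneous
  transients), dose–response tables and three-compartment occupancy, all
  with ground truth.

## Worked example

```r
library(opiometrics)

# a 10-minute synthetic withdrawal session with ground truth
ses <- gen_pose_session(pose_scenario(duration_s = 600, jump_rate = 2, seed = 1))
track <- correct_coordinates(ses$track,
  protect_frames = candidate_jump_frames(ses$track))
track <- calibrate_arena(smooth_coordinates(track))
kin <- compute_kinematics(track)
event_table(track, kin)
#> <event_table> 15 jumps, 307.3 s immobile, 23.35 m travelled
nrow(ses$truth$jumps)          # ground truth
#> [1] 15
```

The session contained 15 programmed jumps; the detector recovered all 15,
and roughly half the session is scored immobile, as the behaviour program
dictates. Photometry follows the same pattern — generate, correct,
detect:

```r
ph <- gen_photometry_session(photometry_scenario(
  injection_response = c(onset = 300, amplitude = 0.3, sign = 1, tau = 300),
  seed = 1))
rec <- compute_dff(fit_isosbestic(ph$recording))
tr <- detect_transients(rec)
print(head(tr, 3), digits = 3)
#>    time height prominence
#> 1  96.7 0.0942     0.1017
#> 2 122.2 0.0498     0.0563
#> 3 127.6 0.0503     0.0571
c(detected = nrow(tr), truth = nrow(ph$truth))
#> detected    truth
#>      124      131
compute_auc(rec$dff, rec$t, c(300, 1500))
#> [1] 76.5
```

124 of 131 generated transients pass the 2-SD prominence rule (the
misses are overlapping pairs), and the post-injection AUC integrates the
0.3 ΔF/F injection response over 20 min. Finally, an occlusion
dose–response experiment (9 subjects, 10 % noise, saline + six doses):

```r
tab <- gen_dose_response(doses = c(0, 60, 120, 150, 180, 210, 300),
  n_subjects = 9, top = 1, bottom = 0, ic50 = 187.2, hill = -2.33,
  cv = 0.1, seed = 1)
fit_logistic4(tab, seed = 1)
#> <dose_response_fit> IC50 = 175.2, hill = -2.52, top = 1, bottom = 0.0765 (RSS 0.172, n = 54)
```

A single 9-mouse experiment recovers the generating parameters to within
sampling error; across 200 replicates the median estimates are within a
fraction of a percent (see `recover_dose_response()`).

An end-to-end run from one config is available via `run_pipeline()` (list
or YAML; see `?run_pipeline`), with a thin command-line wrapper in
`inst/scripts/opiometrics.R`.

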