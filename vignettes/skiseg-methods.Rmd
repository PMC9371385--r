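---
title: "Methods: unsupervised segmentation of skiing days from pocket IMU data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unsupervised segmentation of skiing days from pocket IMU data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A smartphone in a skier's trouser pocket records tri-axial acceleration
(m/s²) and angular rate (rad/s) continuously over a day on the mountain.
Most of that day is not skiing: lift rides, queueing, standing, walking.
`skiseg` splits such a recording into `Skiing` and `Not_Skiing` intervals
without any labelled training data, so that runs can be catalogued and
analysed downstream. The working assumptions are:

* skiing shows sustained, roughly periodic turn oscillations (short turns
  near 1 Hz, long carved turns nearer 0.3 Hz) in the horizontal plane;
* everything else is gravity-dominated with broadband low-amplitude noise;
* any genuine skiing activity lasts at least 30 s;
* the phone's orientation in the pocket is arbitrary and may change
  abruptly mid-session when the user checks the phone.

## Pipeline

`detect_skiing()` chains the stages below; each is exported for
independent use.

**Orientation tracking.** Body-frame axes are meaningless across users and
re-pocketing events, so the accelerometer is first rotated into a
gravity-aligned world frame (+Y up). Attitude is tracked per sample by a
quaternion complementary filter: strapdown integration of the gyroscope
(accurate over short horizons, drifts over long ones) plus a small
per-step correction rotating the world-frame image of the measured
acceleration toward +Y (the accelerometer is unbiased over long horizons
but noisy over short ones). The accelerometer trust per step is
`orientation_gain = 0.02` at the 50 Hz operating rate — a tilt-error time
constant of roughly one second, slow enough that proper acceleration
during a turn does not bend the attitude, fast enough to absorb a pocket
re-orientation within a few seconds. Heading about the gravity axis is
unobservable without a magnetometer; initial yaw is fixed at 0 and yaw
drift is accepted, which is harmless here because all downstream features
are yaw-insensitive up to a rotation of the horizontal axes within a
window.

**Two-stage filtering.** All six world-frame channels are smoothed by a
centered moving average (`ma_window = 0.5` s, shrinking at the edges, DC
gain 1) followed by a zero-phase Butterworth low-pass
(`lp_cutoff = 3` Hz, order 4, forward–backward with odd-reflection
padding of 10/cutoff seconds so the IIR startup transient dies in the
padding). 3 Hz keeps every plausible turn frequency (≤ 1.5 Hz) with
margin and removes pocket shake and snow chatter. The 0.5 s moving
average attenuates the fastest short-turn oscillations by up to tens of
percent of amplitude; this is deliberate — detection rests on the
energy contrast between skiing and idle windows, which survives — but it
is why clean-signal reconstruction tests use slow carved-turn
frequencies.

**Windowed features.** The filtered channels are cut into sliding windows
(`window_size` seconds, step `sliding_rate × window_size`; a trailing
incomplete window is dropped; `n` samples at rate `r` count as `n/r`
seconds of signal). Per channel and window the package computes nine
summary statistics (mean, SD, RMS, min, max, median, variance, raw median
absolute deviation, energy = mean square) on the raw samples and again on
the normalized autocorrelation at nonnegative lags; four level-crossing
counts (mean and the 25th/50th/75th percentiles — the "k% crossing"
levels are read as window percentiles, which makes the 50% level the
median) on both domains; and the mean and median of the periodogram of
the detrended window. One signal-magnitude-area value
(`mean(|ax| + |ay| + |az|)`) is added per window: 169 features.
The autocorrelation domain is the workhorse: periodic turn patterns keep
high autocorrelation at the period lag while noise decays immediately, so
skiing windows carry visibly more autocorrelation energy.

Features are min–max scaled per column to [−1, 1] over the session being
analysed (the normalized feature set, NFS; constant columns map to 0).
Optionally PCA reduces the NFS to the leading components holding
`variance_kept = 0.95` of the variance, with a deterministic sign
convention (largest-magnitude loading positive).

**Two-cluster detection.** Windows are clustered into exactly two groups
by k-means (10 restarts, fixed seed), a full-covariance Gaussian mixture
(via `mclust`, which initialises EM from model-based hierarchical
clustering — deterministic), or Ward agglomeration; crossed with the two
feature sets this gives the six candidate models. Cluster ids are
arbitrary, so the Skiing cluster is identified as the one with the larger
mean raw-window accelerometer energy, with exact ties going to the
smaller cluster (skiing is the minority of a day). Because a two-group
clusterer splits even a single-activity session (idle windows separate
along slow drift), the two clusters are accepted as distinct activities
only if their mean summed accelerometer variances differ by at least a
factor `min_var_ratio = 4` — in synthetic regimes idle-only splits sit
near 1.1 and true skiing/idle splits near 35–80, so the threshold is far
from both. Below the threshold the whole session is labelled Not_Skiing.

**Segments and the 30 s rule.** Each sample takes the majority class of
the windows covering it (ties → Not_Skiing); maximal constant-class
stretches become segments; Skiing segments shorter than
`min_duration = 30` s are relabelled Not_Skiing (not deleted — the
timeline stays covered for per-sample scoring) and merged with their
neighbours.

## Evaluation

Scoring is per sample against time-labelled ground truth. Besides
accuracy and the all-Not_Skiing majority baseline, two chance-corrected
clustering metrics are computed from the label contingency table:

* **ARI** = (RI − E[RI]) / (max RI − E[RI]), with RI the fraction of
  sample pairs grouped consistently in both labelings;
* **NMI** = I(truth; prediction) / √(H(truth) H(prediction)), natural
  logs (any consistent base cancels in the ratio), 0·log 0 = 0.

Both are 1 for identical labelings and ≈0 for independent ones. On long
imbalanced sessions accuracy saturates near the baseline while NMI/ARI
still expose over- and under-segmentation, which is why the report flags
"high accuracy, low clustering metrics". Degenerate conventions: if both
labelings are single-cluster NMI is defined as 1, if exactly one is,
as 0; both cases carry a `degenerate` flag rather than being scored
silently. The contingency-table Rand index is verified in the tests
against a brute-force all-pairs count, and ARI against an independent
implementation (`mclust::adjustedRandIndex`).

`run_grid()` evaluates every combination of window sizes 3–10 s and
sliding rates {1.0, 0.8, 0.5, 0.2} (overlaps 0/20/50/80%; 32
combinations) for the 6 models, aggregates mean and SD per setting over
sessions, and ranks by accuracy with ties broken by ARI then NMI. The
shipped default — k-means on PCA features, 8 s windows, sliding rate
0.5 — is the strongest general-purpose setting of that grid.

## The synthetic-data generator

Real labelled skiing days are scarce, so `generate_session()` produces
sessions with exact ground truth. Its defaults are the package's standing
study conditions, chosen once as a plausible recreational-skiing regime:

* runs of 40–90 s separated by 60–120 s idle gaps (`random_session_spec`),
  3–7 runs per session;
* turn frequencies drawn from [0.3, 1.2] Hz; turn oscillation injected in
  quadrature on the lateral and vertical body axes at `turn_amplitude =
  3` m/s², with a matching 0.3 rad/s sinusoidal roll rate on the
  gyroscope;
* accelerometer noise 0.3 m/s² SD in idle, 0.5 m/s² during runs; gyro
  noise 0.02 rad/s;
* gravity 9.81 m/s² rotated by a random (or specified) static phone
  attitude; optional abrupt re-orientation events; optional 2–5 s linear
  semi-skiing amplitude ramps at run boundaries (off by default);
* sampling at 50 Hz by default — the pipeline's recommended operating
  rate; the I/O layer supports native 500 Hz recordings and resamples by
  linear interpolation (downsampling only).

What the generator does *not* emulate: terrain and slope dynamics,
speed-dependent turn radii, technique differences between skiers,
non-stationary noise (snow quality), walking or other structured
non-skiing activities, and sensor imperfections beyond white noise (bias,
scale, temperature drift). Passing the recovery tests therefore shows the
pipeline is correct under its own assumptions — periodic runs against
gravity-dominated idle — not that the published field accuracies transfer
to any particular real recording.

## Numerical choices and degenerate inputs

* Quaternions are renormalised after every product; unit norm is enforced
  to 1e-9. Antiparallel shortest-arc alignments take a deterministic
  perpendicular axis.
* A zero accelerometer sample carries no gravity information: tilt
  correction is skipped with a warning.
* Energy is the mean square (length-invariant across window sizes);
  MAD is the raw median absolute deviation (constant = 1).
* Constant series: autocorrelation defined as 1 at lag 0 and 0 beyond;
  min–max scaling maps constant columns to 0; level crossings at a level
  touched but not crossed do not count (at-level samples inherit the
  previous sign).
* Sessions whose windows are literally identical, or whose two clusters
  fail the variance-ratio gate, are flagged degenerate and labelled
  all-Not_Skiing rather than scored silently.
* All randomness (k-means restarts, GMM, the generator) flows from
  explicit integer seeds; fixed seed implies bit-identical output.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
20 sessions of 3–7 runs (8–20 minutes each at 50 Hz) for end-to-end
recovery, 100 random static orientations of 20 s for gravity isolation,
1000-case fuzzing of the 30 s rule, and Monte-Carlo nulls of 200–1000
labelings for the metric checks. These sizes keep a full run in single
minutes on one CPU while leaving the statistical conclusions stable.

## Known limitations

* Yaw drift is unobservable and uncorrected (no magnetometer fusion);
  per-window features are insensitive to it, but horizontal-axis identity
  is not preserved across a session.
* The 30 s rule deliberately suppresses genuine skiing bursts shorter
  than 30 s, and boundary quantisation by fixed windows blurs run edges
  by up to one window — the dominant error term in per-sample accuracy.
* Semi-skiing transitions (slow gliding at run boundaries) are detected
  inconsistently; real data shows the same effect.
* The variance-ratio gate assumes idle phases are dynamically much
  quieter than skiing; a session consisting entirely of vigorous
  non-skiing movement could defeat it.
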