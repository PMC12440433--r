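---
title: "Measuring joint range of motion from 2D pose landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring joint range of motion from 2D pose landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(romkin)
```

## The measurement model

Clinical range of motion (ROM) is conventionally measured with a universal
goniometer, which is cheap and accurate in trained hands but suffers from
interobserver variability. Markerless video goniometry replaces the
observer entirely: a pose-estimation step localizes the major body joints
(wrists, elbows, shoulders, hips, knees, ankles) in every frame of a
motion-task video, a planar angle formula converts joint coordinates into
a joint angle per frame, and the maximum over frames is reported as the
subject's ROM for that task. Because every step is algorithmic, repeated
analysis of the same video is bit-identical — the interrater variance of
the measurement itself is zero by construction.

romkin implements this pipeline for three upper-extremity motion tasks,
each tied to one camera view:

| task               | vertex B | ray BA          | ray BC            | output            | view     |
|--------------------|----------|-----------------|-------------------|-------------------|----------|
| shoulder abduction | shoulder | shoulder→elbow  | shoulder→hip      | raw angle         | anterior |
| shoulder flexion   | shoulder | shoulder→elbow  | shoulder→hip      | raw angle         | lateral  |
| elbow flexion      | elbow    | elbow→wrist     | elbow→shoulder    | 180° − raw angle  | lateral  |

The per-frame angle is

$$\theta = \left| \frac{180}{\pi}\,
  \mathrm{atan2}(BA \times BC,\; BA \cdot BC) \right|$$

with $\times$ the scalar 2D cross product and $\cdot$ the dot product.
The absolute value makes $\theta \in [0, 180]$ and renders the result
invariant to side, to the image-axis convention (origin top-left, y
down), and to rotation, translation, uniform scaling and mirroring of
the landmark set — only the subtended angle matters. For elbow flexion
the supplement is reported so that full extension reads 0°. The
maximum-ROM frame is the earliest frame attaining the largest valid
angle.

The model's central assumption is planarity: all joint motion happens in
a plane parallel to the camera. Out-of-plane motion foreshortens one ray
and biases the angle; elbow flexion (hand toward the mouth) is the task
most affected in practice, and the package deliberately reproduces this
2D behaviour rather than attempting any 3D correction.

## Validity handling

A frame can fail to yield an angle for three reasons, recorded per
sample rather than raised as errors, so one bad frame never aborts a
video:

* `absent-landmark` — a required joint was not detected;
* `low-confidence` — a detection fell below the confidence threshold
  (default 0: disabled, the most literal reading of the measurement
  procedure; set a positive threshold to exclude doubtful detections);
* `degenerate-geometry` — a ray shorter than `eps_len` = 1e-9 px, where
  the angle is undefined.

`max_rom()` requires at least `min_valid` = 1 valid frame and reports
validity counts; `measure()` warns when fewer than 25% of frames are
valid. An optional running-median filter (`smoothing = "median"`,
odd window ≥ 3) can be applied over the valid samples before the max is
taken. It is off by default because the unsmoothed argmax is the literal
procedure; with landmark jitter the max of a noisy series is positively
biased, and the filter trades a little peak attenuation for robustness.
Enabling it is a deliberate deviation and should be reported as such.

## The synthetic motion generator

There is no deposited patient data, so validation rests on a
ground-truthed generator (`motion_config()` + `simulate_motion()`) that
realizes exactly the planar kinematic model above: a trunk segment fixed
below the shoulder, and

* shoulder tasks: the straight arm (elbow locked) rotates about the
  shoulder from the side of the trunk to the peak angle and back;
* elbow flexion: shoulder and elbow stay fixed (the instruction to
  minimize elbow displacement) while the forearm rotates 0 → peak → 0.

Defaults: 61 frames at 30 fps, shoulder at (240, 160) on a 480×480 px
canvas, upper arm 80 px, forearm 70 px, trunk 120 px — pixel proportions
consistent with a subject filmed from about six feet by a camera at
shoulder height. The angular profile is a raised cosine (smooth, unique
apex); a triangular ramp is available for exercising argmax tie-breaks.
The profile is rescaled so the peak is attained *exactly* at the apex
frame (the earlier central frame on even grids, where symmetry would
otherwise leave the apex ambiguous to one ulp), which is what makes
noise-free recovery testable at 1e-6°.

Noise is modelled as i.i.d. Gaussian jitter on every landmark
coordinate plus whole-frame dropout of the moving arm's landmarks with
probability `dropout_prob`, mimicking limb-level detection failure.
There is no published quantitative noise model for this setting;
`jitter_sd` defaults to 0 and the validation suite sweeps 0–4 px, with
2 px as the stochastic reference condition. Each `simulate_motion()`
call draws from a private stream fully determined by `seed` and restores
the caller's RNG state.

What the generator does **not** emulate: out-of-plane motion, occlusion
and clothing effects, perspective distortion, correlated (non-i.i.d.)
tracking error, or pose-model bias. Passing synthetic recovery tests
therefore demonstrates that the *formula and pipeline* are correct under
the model's own assumptions — not that any particular pose network is
accurate on clinical video.

## The marker backend

To exercise the full frames-to-ROM path without downloadable network
weights, `render_motion()` rasterizes each frame as colored fiducial
disks (radius 5 px) on black, optionally with neutral dark-grey stick
segments, and `marker_backend()` detects them: per-channel absolute
color matching (tolerance 30 on 0–255 channels, no color-space
conversion), connected-component labelling, the largest component of at
least `min_blob_area` = 4 px wins, ties broken toward the component with
the smallest (row, col) top-left pixel, centroid reported with the
pixel-center convention. The built-in 12-color palette keeps every pair
of reference colors at least 85 apart in some channel, above the
2 × tolerance separability bound the constructor enforces. The detector
is exact to a fraction of a pixel on rendered disks (≈ 0.07 px RMS in
the validation runs) and bit-reproducible.

The adapter for a pretrained pose network (`dnn_backend()`) is a
contract, not a bundled model: weights and the keypoint-index-to-joint
mapping are user-supplied and validated at construction (files must
exist locally; every tracked joint must be mapped or declared missing;
keypoints below a 0.1 confidence threshold are reported absent).

## Agreement statistics

The validation toolkit mirrors how such tools are assessed against
manual goniometry:

* **Mean difference** — `mean(|x−y|)` by default; the signed mean is
  available, and `|signed| ≤ absolute` always. Published comparisons
  typically discuss magnitudes, hence the absolute default.
* **Pearson correlation** and **simple-regression R²**, with the
  identity `R² = r²` holding to 1e-12.
* **ICC**, two-way random effects, computed from the ANOVA mean squares
  of the subjects×raters table. The default form is absolute agreement
  for a single measurement (ICC(2,1)),
  $(MS_R − MS_E) / (MS_R + (k−1)MS_E + \tfrac{k}{n}(MS_C − MS_E))$;
  consistency and average-measure variants are exposed. The same
  function applied to a 2-column subjects×methods matrix serves as the
  interclass correlation between two methods.
* **Interpretation bands** — ICC: unacceptable < 0.20 ≤ questionable
  < 0.40 ≤ good < 0.60 ≤ very good < 0.80 ≤ excellent; CV: low < 10% ≤
  moderate < 20% ≤ high. The conventional cutoff lists are printed with
  small gaps (0.40–0.41, 0.60–0.61, 0.80–0.81); the half-open convention
  at the lower printed cutoff closes them so every value receives
  exactly one label.
* **Per-subject coefficient of variation** (100·sd/mean, sample sd),
  averaged across subjects.
* **Paired Student t test**, two-sided, on per-subject differences.
* **Sample size** for detecting a mean paired difference δ with
  difference-sd σ: the normal approximation
  $n = \lceil ((z_{1−\alpha/2} + z_{power})\,\sigma/\delta)^2 \rceil$,
  which gives n = 30 for δ = 5°, σ = 9°, α = 0.05, power = 0.85. A
  noncentral-t variant (`method = "t"`) is offered and is slightly more
  conservative (31–32 for the same inputs). The power domain is
  `[0.5, 1)`; at power = 0.5 the power quantile is exactly zero, a
  useful closed-form boundary.

All dispersion uses the sample (n−1) convention.

## Numerical choices

* Degenerate rays: `eps_len` = 1e-9 px; below it the frame is invalid,
  not an error.
* Argmax ties: earliest frame, for reproducibility.
* The atan2 form is numerically preferable to `acos` of the normalized
  dot product, which loses several digits near 0° and 180°; the test
  suite's independent oracle therefore evaluates the identical arccos
  quantity through the stable half-angle form
  $2\,\mathrm{atan2}(\|\hat u − \hat v\|, \|\hat u + \hat v\|)$.
* CSV round trips preserve coordinates to six decimal places; absence
  is encoded by row omission (a `(0,0)` sentinel is a valid pixel), and
  an explicit `n_frames` header keeps wholly-dropped frames countable.

## Problem sizes in the validation suite

The suite and the acceptance script use 61-frame clips (2 s at 30 fps),
50 seeded replicates per stochastic condition, jitter levels
{0, 1, 2, 4} px, 10⁵ random vector pairs for the angle oracle and 100
random complete rater matrices (n ≤ 12 subjects, k ≤ 8 raters) for the
ICC oracle — sizes chosen so each property is measured with comfortable
margin while the whole validation remains quick on a laptop.

## Known limitations

* Strictly 2D: out-of-plane motion biases angles, most visibly for
  elbow flexion; this mirrors the method being modelled and is left
  uncorrected by design.
* Single subject per frame; no tracking, no camera calibration.
* MP4/AVI containers are not decoded directly: inputs are landmark
  CSV/JSON files, in-memory frame arrays, or PNG frame directories.
  Extracting frames from a video container is left to standard external
  tooling upstream of `estimate_sequence()`.
* The maximum over frames is an extreme-value statistic: under landmark
  noise it is positively biased, growing with jitter. The median filter
  mitigates but does not remove this.

## A worked example

```{r example}
cfg <- motion_config(task = "shoulder_flexion", side = "right",
                     peak_angle = 135, n_frames = 61, fps = 30,
                     jitter_sd = 1, seed = 42)
sim <- simulate_motion(cfg)
m <- measure(sim$sequence, "shoulder_flexion", "right")
m
sim$truth$true_max
```

```{r agree}
raters <- read_rater_csv(system.file("extdata", "synthetic_raters.csv",
                                     package = "romkin"))
reliability_report(raters)
```
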