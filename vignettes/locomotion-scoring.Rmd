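---
title: "Locomotion scoring from keypoint tracks: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locomotion scoring from keypoint tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bovigait)
```

## The problem

Lameness is among the costliest diseases of dairy cattle, and the standard
detection instrument — visual locomotion scoring by a trained observer — is
slow, subjective, and hard to staff at herd scale. A practical alternative
is a side-view camera on the walking passage: a detector finds the cow, a
pose model marks 22 anatomical keypoints per frame, and the lameness
assessment is computed from the keypoint trajectories. `bovigait`
implements everything downstream of the vision models: it consumes
per-frame bounding boxes and keypoints and produces a locomotion grade on
a 7-level scale (a 0.5-step refinement of the 5-level Sprecher scale,
truncated at Sprecher 4) or a binary healthy/lame call.

Three visual signs carry most of the clinical signal, and each is
operationalized as a per-frame indicator:

* **Spine curvature.** A sound cow walks with a flat back; arching grows
  with severity. Two per-frame measures are computed from the five spine
  landmarks (Neck, Spine_1..Spine_4), after normalizing coordinates to the
  frame's bounding box: the *angle ratio* — the angle at Spine_2 between
  rays to the Neck and to Spine_4, in degrees over 180 — and the *distance
  ratio* — the Neck-to-Spine_4 chord over the polyline length through all
  five points. Both are 1 for a straight spine and fall as it arches.
* **Head position.** Severely lame cows drop the head when loading the
  affected limb. The Eye height is scaled between the lowest visible hoof
  (0) and the highest spine point (1); the series is only recorded around
  detected steps, since the drop is a stance-phase event.
* **Track-up (same-side inter-leg distance).** A sound cow's rear hoof
  lands in or near the print of the ipsilateral front hoof. The |x|
  distance between same-side hooves, divided by the cow's height, is
  recorded around each rear-hoof touchdown; its per-step minimum measures
  the landing shortfall.

## Coordinate conventions

Pose output arrives in image coordinates (y grows downward). All analysis
runs in a canonical frame: y up (the head normalization reads naturally as
"between ground and back line") and motion rightward. The vertical flip
uses the track-wide maximum bounding-box bottom edge — a per-frame
reference would inject box jitter into every vertical kinematic — and
leftward passages are mirrored about the track-wide horizontal extent.
Both are isometries, so no distance-based quantity is affected. When the
recording direction is missing, it is inferred from the sign of the median
per-frame displacement of the box center, which is robust to keypoint
noise. Coordinates are 0-based pixel centers; boxes are corner-coded
half-open intervals.

Invisible keypoints are never silently filled: gaps of at most
`io.max_gap` frames (default 3) flanked by visible frames are linearly
interpolated and flagged as imputed; anything longer, or touching the
track ends, stays missing and invalidates the frames that need it.

## Step detection

The head and leg indicators are gated on steps, which the source material
uses but never defines; the detector here is deliberately simple and
relative. A hoof is in stance when its smoothed horizontal speed (central
difference, 5-frame moving average) is at or below `gait.speed_frac`
(default 0.15) times the track-wide 95th-percentile speed, for at least
`gait.min_run` frames (default 3 at 30 fps, scaled with frame rate). Each
swing-to-stance transition is a step, with the touchdown at the first
stance frame. The relative threshold makes the detector exactly invariant
to uniform spatial scaling; the defaults recover the synthetic generator's
stance phases to within one frame on noiseless data (the tests assert a
two-frame tolerance).

A step's *initial phase* — needed by the head aggregate — is the first
`ceil(0.2 x stance length)` frames of the stance interval; the fraction is
configurable (`gait.initial_phase_frac`) and fps-robust by construction.

## Aggregation

Per-frame series are collapsed to per-passage scalars for the expert tree
and the ML backend:

* **Spine.** Each channel is smoothed (uniform kernel, `aggregate.window`
  default 5 frames, about 167 ms at 30 fps, with reflect padding over the
  valid frames), local minima are found (a plateau flanked by larger
  values counts once, at its floored center; endpoints never count), and
  the minima are averaged — arching is deepest mid-stride, so the minima
  carry the signal. Monotone passages with no interior minimum fall back
  to the global minimum so the aggregate always exists. The two channel
  aggregates are blended with weight `aggregate.spine_blend` (default 0.5;
  the original operating points were split-specific but unpublished).
* **Head.** `head_min` is the global minimum of the smoothed step-gated
  series. `head_drop` is computed per hoof — the mean over that hoof's
  steps of (initial-phase mean minus within-stance minimum) — and the
  per-hoof maximum is reported. The head bob of a lame cow is phase-locked
  to loading of the *affected* limb; averaging drops across all four
  hooves' steps dilutes the signal with limbs whose stance is out of phase
  with the bob (on the synthetic generator, pooling recovers only about a
  third of the injected amplitude, while the per-limb maximum recovers it
  to within the smoothing loss). The maximum reads out the affected limb
  without requiring its identity.
* **Legs.** Each pair (FR-BR, FL-BL) is gated on its rear hoof's
  touchdowns — the measure asks where the rear hoof lands relative to the
  front track — over a window of `indicators.leg_window` frames (default
  10 at 30 fps, scaled with fps) on each side of the touchdown. Per step
  the window minimum is taken; minima are averaged over steps, then the
  two pair values are averaged. If only one pair has usable steps its
  value is used, with a warning.

Zero-step passages produce sentinel (`NA`) head and leg features. The
expert tree routes sentinels to the healthy side of head decisions
(absence of evidence of bobbing), and the ML backend imputes them with
training-set channel medians — both rules are deterministic.

## The three backends

**Expert tree.** A fixed decision tree mirrors how veterinarians combine
the signs: severe head bobbing decides grade 7 first; otherwise the spine
splits grades 1-2 from 3-6 (and 1 from 2); the legs split 3 from 4-6; the
head splits the merged 4-5 from 6. Grades 4 and 5 are merged, as their
presentations differ only slightly; the merged leaf is emitted as ordinal
4.5 (configurable), which scores as within-one of both true grades. The
thresholds are configurable; `calibrate_thresholds()` reproduces the
elicitation role the experts played by placing each threshold at the
midpoint of the class-conditional medians of the two grades adjacent to
its split. Routing is monotone in every feature, and ties take the branch
stated in the documentation. One sentence of the source material suggests
the spine may "verify" the head's grade-7 call; no verification rule is
specified, so the pure tree is implemented and the question noted here.

**ML backend.** Six families over the four aggregated features
(spine_value, head_min, head_drop, legs_value — the head algorithm yields
two values, and both are passed): CART decision tree, random forest,
AdaBoost (SAMME over shallow CART trees), gradient boosting (xgboost),
k-nearest-neighbours, and support-vector regression whose output is
rounded half-up to integer grades and clipped to 1..7. Evaluation uses
leave-one-out cross-validation; each row is predicted by a model that
never saw its label (a poisoning test asserts this). Hyperparameters are
library defaults with a fixed seed, recorded in the model spec.

**Sequence classifier.** A CNN-BiLSTM consumes the five per-frame
channels directly: three 1-D convolutions with filters rising 128, 192,
320 (kernel 3, ReLU), a bidirectional LSTM with 256 units per direction
returning sequences, a second bidirectional LSTM with 512 units
summarizing the sequence, and a dense softmax over the seven grades,
trained with categorical cross-entropy and Adam. The layer widths and
depths of the recurrent stack follow the published architecture; the
convolution count (3), learning rate (2e-3), batch size (16), dropout
(0, on the convolutional output when enabled), and epochs (30) were not
published and are package defaults. The network is implemented directly
on BLAS-backed matrix operations with the LSTM time loops in compiled
code; the backward pass is verified against numerical gradients in the
test suite. Passages are linearly resampled to a fixed length `T`
(default 120, about 4 s at 30 fps) so batch shapes are static — resampling
was chosen over padding because passage lengths vary and masking adds
nothing once the indicator series is smooth. Channels are standardized
with training-set statistics stored in the model. Time-series
augmentation (Gaussian jitter, moving-average smoothing, random time-point
dropout with re-interpolation) is provided as a seeded, deterministic
transform. Cross-validated training at leave-one-out granularity is
supported through the same functions; the shipped evaluation uses a
stratified holdout at the cohort sizes below.

## The synthetic gait generator

Real passage recordings are restricted, so every stage is validated on a
kinematic simulator with known ground truth. One passage is a rightward
crossing at 30 fps (emitted in raw y-down image coordinates so ingestion
is exercised): spine points ride on a circular arc whose sagitta is a
fixed fraction of the chord per grade (0, 0.02, 0.05, 0.08, 0.11, 0.14,
0.18 for grades 1..7); hooves alternate stance (fixed print) and swing
(smoothstep advance with sinusoidal lift; defaults 20 + 14 frames, a
1.13 s stride); each rear hoof touches down while its ipsilateral front
hoof is still in stance, landing `track_up_offset x height` behind the
front print (0, 0.02, 0.06, 0.12, 0.18, 0.26, 0.35 by grade), so the
per-step minimum inter-hoof distance equals the injected offset exactly
on noiseless data; and the Eye dips mid-stance of the affected limb
(default BR) by `head_bob_amp x height` (0 for grades 1-5, 0.08 for 6,
0.25 for 7), starting after the step's initial phase so the
initial-minus-minimum aggregate can recover it. Gaussian keypoint noise
(default sigma 2 px against a 200 px cow height, a realistic pose-model
error) is added last; the bounding box is the tight box over the noisy
points plus a 5 px margin.

The per-grade maps are calibration constants of the simulator — chosen
once so that the grade semantics (straight spine and perfect track-up at
grade 1; pronounced deviation and head bobbing at 6-7) hold and the three
designed signals are separable — not claims about real cows. What passing
tests show is therefore that the pipeline recovers *designed* pathology
through the full ingestion-to-decision path, that its geometry is exact,
and that its decision logic is faithful; they do not show field accuracy
on real herds, where keypoint failure modes (occlusion, identity swaps,
non-Gaussian error) and biological variability are richer than the
simulator emulates.

## Numerical choices and degenerate inputs

* Circle fits use the algebraic (Kasa) least-squares formulation on
  centered coordinates; collinearity is declared at a normal-equation
  condition number above 1e8 or a fitted radius above 1e6 times the point
  spread, and degenerate fits fall back to the raw three-point angle
  (which tends to 1, the straight-spine limit).
* The angle indicator defaults to the raw three-point angle
  (`indicators.angle_mode = "raw"`). The alternative — projecting the
  landmarks onto the fitted circle before taking the angle — is
  implemented and selectable, but measurement showed it *amplifies* noise
  for near-straight spines: with 2 px noise the algebraic fit latches
  onto small circles through the noise, and the projected grade-1 angle
  ratio averages 0.90 versus 0.98 raw, inverting the ordering of grades 1
  and 2. The raw mode keeps the grade ordering strict.
* Smoothing windows must be odd; even windows are rejected rather than
  silently recentered. Window 1 is the identity.
* Equality ties at expert-tree thresholds take the documented branch, so
  calibration-then-classification is exactly self-consistent.
* All randomness (simulator noise, ML seeds, network initialization and
  batch order, augmentation) flows from explicit integer seeds; reruns
  are bit-identical.

## Problem sizes used by the shipped checks

The packaged evaluations run on cohorts sized for a desk machine: 140
passages (20 per grade, noise sigma 2 px) for the feature-monotonicity and
ML leave-one-out checks; 70 noiseless passages (10 per grade, sequence
length 120, 30 epochs) with a stratified 14-passage holdout for the
sequence-classifier training check, plus a permuted-label control at the
same setup; 200 random tracks for the invariance sweep. These sizes were
chosen so each property is measured with comfortable margins while the
whole suite stays a desk-scale run.

## Known limitations

* The simulator is a kinematic sketch: no perspective, no occlusion, no
  keypoint identity swaps, one affected limb, and grade-deterministic
  pathology maps. Field data will be harder.
* The expert-tree thresholds shipped by calibration are synthetic-cohort
  operating points; real-farm thresholds must be calibrated on expert
  labels from the target herd.
* The original split-specific spine blend ratios and the full
  hyperparameter search of the sequence classifier are unpublished; the
  defaults here are documented but not claimed faithful to the originals.
* Per-limb lameness attribution, stride-length/speed traits, and 3-D
  reconstruction are out of scope.
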