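---
title: "Closed-loop slice tracking: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop slice tracking: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cathtrack` simulates prospective slice tracking of a gadolinium-filled
balloon catheter as a closed loop: image formation from a digital
phantom, slice- and stack-based segmentation, 3D localization, and the
Calibration/Runtime state machine that re-prescribes the next stack.
This vignette explains the underlying models, the parameters that
matter, and the choices made where the design was genuinely open.

## The tracking procedure

The controller has two modes. **Calibration** acquires a fixed stack of
contiguous slices covering the anticipated catheter trajectory, with a
90° nonselective saturation prepulse so that tissue is nulled and the
short-T1 balloon dominates the image. If the balloon is found, the
controller switches to **Runtime** and centres a 3-slice stack (pSAT 50°)
on the detected position; if not, Calibration repeats. Each Runtime stack
has three outcomes:

1. balloon in the central slice — no change;
2. balloon in an outer slice — the next stack is shifted by exactly one
   slice thickness along the stack normal, toward that slice;
3. balloon not identified — no change, and after `miss_threshold = 5`
   consecutive misses the controller reverts to Calibration.

Feedback is delayed by a latency queue: with `latency_dynamics = 1`
(default) the prescription computed from stack $d$ governs acquisition
$d+1$. The queue holds the prescriptions of the next $L$ acquisitions;
each `advance_state()` pops the head and pushes the newly emitted
prescription, so larger $L$ models slower reconstruction/inference
feedback. Because queued prescriptions can be stale at $L > 1$, the state
machine branches on the mode of the stack actually acquired, which
coincides with the controller mode at $L = 1$.

The invariant that makes the loop safe is geometric: with per-dynamic
through-plane motion at most $T/2$ (half the slice thickness) and latency
1, a balloon detected in an outer slice is recaptured by the $\pm T$
shift before it can leave the $3T$ slab. The property suite verifies this
over seeded sessions rather than assuming it.

## Image formation

A slice image is

$$ I(p) \;=\; \cos(\alpha)\, \bar V(p) \;+\; w\, B\,
   \exp\!\big(-d(p)^2 / 2\sigma^2\big) \;+\; \varepsilon(p), $$

clipped at zero, where:

* $\bar V(p)$ is the slab-averaged phantom intensity: the mean of $K = 5$
  equispaced sample planes through the slab, each resampled by trilinear
  interpolation. This captures thick-slice averaging at a fraction of the
  cost of full integration; $K$ is exposed as `n_slab_samples`.
* $\cos(\alpha)$ is a phenomenological saturation model: a 90° prepulse
  nulls tissue exactly, a 50° pSAT prepulse leaves $\cos 50° \approx
  0.64$ of it. Full Bloch/bSSFP physics is deliberately out of scope —
  the tracking logic consumes contrast, not spin dynamics.
* the balloon term is *not* attenuated by the prepulse (short-T1
  gadolinium recovers immediately). $w \in [0,1]$ is the through-plane
  partial-volume weight: the fraction of the balloon's extent
  $[o-r,\,o+r]$ overlapping the slab $[-T/2,\,T/2]$, normalised by $2r$.
  Because contiguous slabs partition the through-plane axis, the weights
  of a covering stack sum to exactly 1 — the balloon "leaks" into
  adjacent slices exactly as much as it leaves the central one.
* the in-plane footprint is a Gaussian whose half-maximum contour sits at
  the balloon radius ($\sigma = r/\sqrt{2\ln 2}$), so the rendered blob
  has the balloon's visual size.
* $\varepsilon$ is zero-mean Gaussian noise with SD `noise_sd`, clipped
  at zero — a Rician approximation that is adequate at moderate SNR and
  degenerate on fully saturated backgrounds (see the detector notes).

Conventions are fixed explicitly because nothing forces them: world
coordinates in mm, right-handed; voxel and slice indices 0-based; a
voxel's world position is its centre; slice $i$ of a stack is centred at
$c + (i - (n-1)/2)\,T\,\hat n$; image pixel (row, col) maps to the
in-plane axes (v, u) with pitch FOV/matrix about the image centre.

Default balloon geometry is radius 4 mm and brightness 300 (3× the
100-unit tissue level). These are configuration values, not claims about
any particular catheter: the physical balloon size and signal level vary
with the device and the contrast dilution.

## The phantom preset

The `"phantom"` preset defines the study conditions used by the
acceptance runs and fixes every free quantity once:

* a 320 mm water-bath body (64³ voxels at 5 mm, tissue level 100,
  multiplicative texture SD 2 %) spanning the 300 mm FOV, carrying a
  tube (intensity 105) and a sphere (intensity 80). The structures are
  deliberately low-contrast — visible in images but several noise SDs
  below the detection threshold — because the classical stand-in
  detector has no shape model and a phantom is, in reality, mostly
  smooth water signal;
* `noise_sd = 2`, giving a balloon z-score of order 100 (the "high CNR"
  regime in which the reference experiments report perfect detection);
* a through-plane zigzag trajectory (±30 mm at 4 mm/dynamic, 0.3 mm
  isotropic jitter), keeping per-dynamic motion under $T/2 = 5$ mm;
* 9-slice Calibration / 3-slice Runtime stacks, 10 mm thickness,
  matrix 128, 100 dynamics.

The `"loss"` preset adds scripted balloon-loss events (teleport +30 mm
through-plane at dynamic 40, return at dynamic 70), each of which must
produce exactly five consecutive misses, a revert, and a recalibration.
The patient-style presets (`"patient1"`–`"patient3"`) change geometry
(12-slice coronal Calibration, sagittal Runtime, 6–10 mm slices,
matrices 112–160, 59–117 dynamics) to exercise mixed orientations.

Problem sizes were chosen so that a full closed-loop session takes a few
seconds and the whole verification suite minutes on one CPU; they are
desk-scale by design, not scaled-down replicas of any clinical dataset.

## Detectors

**Classical backend.** Each pixel's robust z-score against the image
median and MAD, thresholded at `z_threshold = 5`; 4-connected components;
area filter (`min_area_px = 3`, `max_area_px = 400`); per-region
intensity-weighted centre of mass. One numerical subtlety matters: on a
fully saturated Calibration background roughly half the pixels are
exactly zero after clipping, so the sample MAD is either exactly zero or
a tiny positive value — both grossly underestimating the noise scale and
flooding the image with "detections". The scale therefore falls back to
the SD whenever the MAD is below a tenth of it (which subsumes the exact
MAD = 0 case). The area filter also protects against the opposite
pathology: when most of the field of view is air, the entire body
cross-section crosses the threshold as one giant component and is
rejected by `max_area_px`.

**Trainable backend.** A small encoder–decoder convolutional network
(3×3 convolutions + ReLU, 2×2 mean-pool downsampling, nearest-neighbour
upsampling with skip concatenation, 1×1 output head), trained with a
pixelwise Dice-plus-cross-entropy objective and Adam
(`learning_rate = 1e-2`, `epochs = 10`, `batch = 8` by default; all pure
R, deterministic for a fixed seed). The architecture is intentionally far
smaller than the large pretrained encoders used on scanners: the
framework property being exercised is detector-agnostic tracking, not
network capacity. After training, the decision threshold is calibrated
on the validation split — it is set halfway between the worst background
peak probability (outside a margin around the truth mask on every
validation image) and 1, clipped to [0.5, 0.99]. This keeps the deployed
backend free of a user-tuned threshold while controlling false positives
on structured backgrounds, which would otherwise let the tracker "find"
a balloon during loss windows and never revert.

Both backends meet the same contract: disjoint 4-connected regions with
area limits applied, so `select_stack_region()`, the state machine and
all metrics are backend-blind.

## Semi-artificial training data

`generate_training_set()` reproduces a generation *procedure*, not any
particular dataset: anisotropic 2D Gaussian balloons with each σ drawn
uniformly from {1.5, 2.5} px, rotation uniform on [0°, 360°), and peak
amplitude uniform on 200–400 % of the underlying image signal,
superimposed at positions drawn from a region-of-interest mask. Three
quantities the procedure leaves open are fixed here as design choices:

* the "underlying signal" is the mean background intensity in the 5×5
  neighbourhood of the injection centre (robust to single-pixel noise;
  a config switch falls back to the global positive mean when the local
  neighbourhood is empty);
* the ground-truth mask is the half-maximum super-level set of the
  Gaussian — an ellipse matching the balloon's visual extent, growing
  with σ;
* the amplitude distribution over its stated range is uniform (the
  minimal assumption), and 10 % balloon-free negatives are added so the
  detector's specificity can be trained and verified — a pure
  positives-only corpus cannot measure false positives.

The default 0.69/0.31 train/validation split mirrors the roughly
two-thirds/one-third division typical of this kind of corpus.

What the generator does **not** emulate: anatomy-specific texture,
coil-profile shading, flow and motion artefacts, or the appearance of
real pSAT patient images. Passing tests therefore demonstrate that the
pipeline and its logic are correct under the stated image model — not
that any particular network generalises to clinical data.

## Evaluation

A detection is a **true positive** when the (rounded, intensity-weighted)
centre of mass of the single evaluated region lies inside the
ground-truth region; at stack level the slice index must also match the
retained truth slice. A mislocalized detection on a truth-containing
slice counts as a single FN rather than FN + FP, keeping one label per
evaluated unit and the confusion matrix well defined. Ratios with a zero
denominator are reported as absent (`NA`), never as zero — a run in
which the balloon never leaves the stack has no balloon-free stacks and
hence no defined stack-level specificity.

Stack-level ground truth mirrors stack-level selection: among slices with
nonempty truth, the one whose truth region has the highest mean image
intensity is retained. When the balloon sits almost exactly on a slice
midplane the two argmaxes are driven by correlated per-slice noise and
can, in principle, disagree, producing a rare FN; the disagreement band
is of order 0.02 mm at the preset noise level, and no such event occurs
in the seeded acceptance runs.

CNR is reported in two forms because the quantity is used with an
unspecified normalisation in practice: the primary definition
$(\mu_\text{balloon} - \mu_\text{bg})/\sigma_\text{bg}$, plus the
relative contrast $100(\mu_\text{balloon} - \mu_\text{bg})/\mu_\text{bg}$
in per cent. The background is an annulus 5–10 px outside the truth
region. Group comparisons (TP vs FN, TP vs FP) use two-sided Welch
t-tests; groups with fewer than two records are skipped with a warning.

A switch to Calibration is **correct** when the true balloon position lay
outside the acquired Runtime slab for *every* dynamic of the
consecutive-miss window that triggered it — the strictest reading; a
switch caused partly by detector misses on a balloon that was actually
in the slab is counted as incorrect.

## Reproducibility and numerical conventions

* A single experiment seed derives per-(dynamic, slice) noise substreams
  (`substream_seed()`), so stacks are bit-reproducible independent of
  acquisition order, and library code never clobbers the caller's RNG
  state.
* Selection ties (equal region intensity) break by larger area, then
  lower slice index; these are exact-equality events with measure zero
  under noise but must be deterministic.
* `classify_outcome()` requires an odd Runtime slice count — the central
  slice is otherwise undefined — and config validation enforces it.
* Degenerate inputs are contracts, not errors: a balloon outside the
  slab yields weight 0; a constant image yields an empty segmentation;
  an empty stack yields `found = FALSE`.
* The per-session tissue term is memoised by slice geometry: Runtime
  shifts revisit centres displaced by exact multiples of $T$, so the
  slab-averaged background is computed once per distinct centre.

## Limitations

* The contrast model is phenomenological; banding, flow enhancement,
  GRAPPA noise amplification and other sequence effects are absent.
* In-plane tracking is recalibration-only: the Runtime stack centre
  moves in-plane only when a Calibration detection re-seats it, matching
  a through-plane slice-shift controller; a balloon drifting far
  in-plane would stay imaged but off-centre.
* "Highest signal intensity" is implemented as the region mean (peak
  intensity is available as a config alternative); the two can differ
  for regions of very unequal size.
* The trainable backend is a desk-scale network trained on synthetic
  data; its numbers say nothing about clinical-grade models beyond the
  correctness of the surrounding pipeline.
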