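---
title: "Scoring rodent engagement from head-mounted fiducial markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring rodent engagement from head-mounted fiducial markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arutrack)
```

## The problem

In operant go/no-go tasks, a rat is cued (here: intracortical
microstimulation) to nose-poke for a reward, or to withhold the poke.
Whether a trial without a poke reflects a *perceptual* miss or simple
*distraction* matters for interpreting psychometric data, but scoring
engagement by watching video is slow and subjective. A cheap, real-time
alternative is to glue a small square fiducial marker (an ArUco-style
black-and-white pattern with a unique id) to the animal's head cap, watch it
with overhead webcams, and classify engagement from the marker's planar
pose.

`arutrack` implements that pipeline end to end:

1. **geometry** — marker center, nose-ward heading, yaw relative to the
   chamber's module wall, region-of-interest (ROI) membership;
2. **detection** — finding the marker in raster frames and fusing
   multi-camera streams;
3. **scoring** — per-frame engagement classification and per-trial labels
   synchronized to the trial timeline;
4. **dynamics** — a windowed probability-of-engagement trace and the
   disengagement time;
5. **metrics** — confusion-matrix validation against manual scoring,
   including the Matthews correlation coefficient (MCC), and the
   motion-blur velocity model;
6. **synthetic** — a seeded session simulator and frame renderer so every
   stage is testable without animals or recorded video.

## The classification model

A frame is **engaged** exactly when

* the marker was detected (occlusion defaults to *distracted* — the
  conservative choice, since an undetected marker carries no evidence of
  task attention);
* the marker **center** lies inside at least one ROI of the detecting
  camera (boundary inclusive); and
* the nose-ward yaw lies in the closed window **[5°, 175°]**.

Yaw is the signed angle of the heading vector — from the marker center
toward the midpoint of the nose-side edge — measured against the module
wall's direction, with the wall normal oriented from the chamber interior
toward the wall. So 90° means facing the wall squarely, 0°/180° grazing
along it, and negative values facing away. The window is deliberately wide
to give the animal leeway in orientation; its endpoints count as engaged.

Two conventions here were genuinely open and are package decisions:

* **Yaw reference.** "90° indicates orthogonality" is ambiguous between an
  edge-relative and a heading-relative angle. We measure the *heading*
  against the *wall direction*, signed toward-wall positive, which makes
  the 5–175° window mean "pointed at the module wall, not grazing or
  turned away". Which physical marker edge faces the nose depends on how
  the mount is glued, so `front_edge` is a configuration knob (0–3).
* **ROI membership** is tested on the marker center, the simplest reading
  of "found within the region of interest", and the boundary counts as
  inside, mirroring the generosity of the wide yaw window.

A trial is scored by the **any-frame rule**: one engaged frame anywhere in
the active window makes the trial engaged, regardless of interleaved
distraction. A trial with no detected frames at all is scored distracted
(not excluded); callers who prefer exclusion can filter on
`n_frames_seen == 0` in the score table. Inter-trial frames are classified
only for the live annotation colors (green/yellow for active
engaged/distracted, purple/pink for inter-trial), never scored.

## Detection

No fiducial-marker decoder exists in the R ecosystem, so the package ships
its own, built for the synthetic validation loop:

* a deterministic **4×4 dictionary** (fixed internal generation seed) whose
  patterns are mutually separated by a rotational Hamming distance ≥ 4,
  rotation-unambiguous, and reflection-distinct — so one misread bit is
  correctable, orientation is never ambiguous, and a mirrored image never
  decodes;
* a **renderer** that rasterizes a marker (black ring, code cells, one-cell
  white quiet zone) under rotation/translation with 3× supersampled
  anti-aliasing and optional linear motion blur along the heading; and
* a **detector**: adaptive binarization at the mid-range intensity,
  connected dark components (EBImage), convex-hull quad fitting, sub-pixel
  edge refinement from dark-to-light intensity crossings along edge
  normals, perspective sampling of the 6×6 cell grid through a
  homography, and dictionary matching over the four corner rotations.

On rendered frames the round trip recovers planted corners to well under
0.1 px (the tests assert 1.5 px) and yaw to well under 2°. Detection
degrades monotonically with blur kernel size and improves with marker size;
the blur-velocity model `blur_velocity()` converts a kernel length to the
marker speed that produces it (2 px ≈ 3 cm/s, 6 px ≈ 8 cm/s at
60 fps / 42 cm / 1920 px).

Multi-camera streams are paired by **nearest timestamp** within half a
frame period (real capture clocks drift; synthetic streams pair exactly),
and detections are OR-ed across cameras. `fuse_streams()` also returns the
frame account — frames seen by camera 1 only, camera 2 only, both, or
neither — whose four categories always partition the paired total, and
fused coverage can never fall below any single camera's.

## Engagement dynamics

Per-trial labels are averaged with a **causal rectangular kernel**: at
evaluation times $t = 1, 2, \dots$ min (step 1 min), the probability of
engagement is

$$p(t) = 100 \cdot \frac{\#\text{engaged trials starting in } (t - 5, t]}
{\#\text{trials starting in } (t - 5, t]}$$

with a 5 min window. The kernel is *backward-looking* ("back-heavy") so the
estimate at $t$ uses only the preceding window and could be computed live
during a session. Decisions where the source procedure was silent:

* trials enter windows by their **active-period start time**;
* startup windows ($t <$ window length) are truncated at the session start
  and flagged, rather than skipped;
* windows holding zero trials yield **missing values, never 0%** — a
  spurious 0 would instantly trigger the disengagement rule;
* disengagement is the **first** defined evaluation below the 50%
  threshold; a `min_consecutive` option requires a sustained run but
  defaults to 1, matching "once the probability fell below".

With dense trials and a hard attention switch at time $\tau$, the first
crossing always lands in $[\tau, \tau + 5]$ min: the causal window must
fill past half with post-switch trials. For trials every 9 s (6 s active +
3 s inter-trial) and a switch at 70 min, that is exactly 73 min — the
value both the brute-force window oracle and `disengagement_time()`
produce in the tests.

## Validation metrics

`confusion_from_labels()` counts TP/TN/FP/FN with engaged as the positive
class; `confusion_from_marginals()` reconstructs the unique 2×2 matrix from
published totals (a matrix is fully determined by total, truly-positive
count, predicted-positive count, and FN; the apparent fourth constraint
$TN + FN = \text{total} - \text{predicted positives}$ is algebraically
implied, so only a negative cell can make marginals infeasible).
`compute_metrics()` returns accuracy, precision, sensitivity, specificity,
F1 (as percents) and MCC. F1 is the plain harmonic mean
$2PS/(P+S)$ on the percent scale, and MCC uses the square-rooted product of
the four marginals. Zero-denominator conventions: precision, sensitivity,
specificity, and F1 are reported missing when undefined; MCC is 0 when any
marginal is zero (the standard convention; note it does *not* apply to a
total-disagreement matrix, whose MCC is −1).

## What the simulator emulates — and what it does not

`sim_config()` defaults encode the study conditions: 32 min sessions, 6 s
active trials, 3 s inter-trial periods, 60 fps, two cameras. The latent
process is **two-state at trial granularity**: every trial before the
planted disengagement time is in the attentive state, every one after in
the distracted state, and the trial's behavioral label is drawn from the
state-conditional engagement probability — 0.9515 while attentive (the
engaged-trial fraction observed in standard-length sessions) and 0.05
after. A per-frame Markov chain would add realism the per-trial scoring
granularity cannot see; the per-trial process is the simplest one that
exercises every downstream stage.

Engaged trials get a base pose sampled inside the ROI with yaw inside the
window; distracted trials violate exactly one gate — half outside the ROI,
half with away-facing yaw — so both gates are exercised. Small per-frame
jitter (σ = 2 px, 2°) is clamped so a frame never crosses its trial's gate,
which keeps ground truth exact by construction. Occlusion is i.i.d.
per-frame dropout per camera; the defaults (80% dropout on camera 1, 35% on
camera 2) reproduce the strong camera asymmetry and ~70% fused coverage of
a real dual-camera chamber, though the published per-camera percentages are
not mutually consistent enough to fit exactly. What the simulator does
*not* model: fur/lighting appearance, correlated (bout-like) occlusion,
camera-specific projective geometry (all cameras share one pixel frame),
grooming-in-ROI false positives, or codec artifacts. Passing tests
therefore demonstrate the *pipeline logic* — geometry, scoring, fusion
accounting, changepoint arithmetic — not appearance robustness on real
video.

`generate_frames = FALSE` produces only the trial timeline and
ground-truth labels from the same latent process, for label-level analyses
(e.g. many replicate changepoint studies) where per-frame geometry is
irrelevant.

## Numerical choices and degenerate inputs

* Image coordinates are raster convention (origin top-left, y down), pixel
  centers at half-integers; all geometry is pure 2D (no camera intrinsics
  — 3D pose is out of scope).
* Yaw is reported in (−180°, 180°] from `atan2`; degenerate inputs
  (zero-length heading, wall endpoints equal, interior hint on the wall
  line, front-edge midpoint at the marker center) are errors, not NAs.
* Point-in-polygon uses the even-odd rule with a boundary tolerance of
  10⁻⁹ px.
* The detector requires the full border ring dark, tolerates one code-bit
  error (half the dictionary's minimum distance), and rejects quads with
  side ratio > 4 or sides < 8 px.
* Trial windows are half-open $[start, end)$ so a frame on a boundary
  belongs to exactly one window.
* Probability of engagement with zero trials is undefined (NA with a
  warning), never 0.

## Problem sizes in the test suite

The suite validates invariants at deliberately modest sizes — simulated
sessions of 2–10 min at 5–10 fps for pipeline properties, one 80 min
session (533 trials) for the noiseless end-to-end recovery, 100 replicate
planted-changepoint sessions at label granularity, 1,000 random confusion
matrices against an independently written textbook oracle, and a handful of
rendered frames per detector property. These sizes are where the asserted
properties are already exact (label recovery, partition identities,
changepoint bounds) or statistically decisive (binomial checks use ±4
standard errors), so larger runs would add time without discriminating
power.

## Known limitations

* The detector is validated on its own renderer's output; real-video
  robustness (lighting, perspective, lens distortion) is untested here.
* Exactly one marker is tracked downstream (`target_marker_id`), although
  the detector returns every dictionary hit in a frame.
* Distraction *causes* (grooming, rearing) are not distinguished — a
  grooming bout inside the ROI with a wall-facing marker scores engaged,
  the known false-positive mode of this classification scheme.
* Disengagement detection has the kernel's resolution: 1 min steps, and a
  bias of up to one window length after a true switch.
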