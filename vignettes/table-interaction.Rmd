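---
title: "Measuring operating-table interaction from pose tracklets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring operating-table interaction from pose tracklets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tableside)
```

## The problem

Operating-room efficiency studies need to know when personnel are
actually working at the operating table, but watching and annotating
video does not scale, and the video itself usually may not leave the
hospital. tableside starts one step downstream of the camera: it
consumes per-frame 2D human pose detections (17 keypoints in the COCO
layout, each with a confidence) and turns them into an interaction time
fraction. No video, no images, no learning — a deliberate choice that
keeps every step auditable.

## The rule set

The model is that a person interacts with the operating table when they
are simultaneously *still* and *in the right position*. Both conditions
are evaluated per pose detection on subposes — small named keypoint
groups — so that a partially occluded person can still be classified.

**Movement.** For a keypoint in a tracklet we take the net Euclidean
displacement between its position at frame $t$ and at frame
$t - f_\mathrm{motion}$. A subpose is still when at least
$M_\mathrm{keypoint}$ of its keypoints shows displacement strictly below
$\tau_m$; a keypoint that is undetected, below the confidence gate
$\gamma_m$, or lacking a displacement endpoint is assumed still. A pose
is still when at least $M_\mathrm{subpose}$ subposes are.

**Position.** The room is annotated once per camera view with three
polygons: where the wrists, shoulders and head of a person standing at
the table should appear. A keypoint counts when detected, at confidence
$\geq \gamma_p$, and inside its polygon; a subpose is positioned when at
least $P_\mathrm{keypoint}$ keypoints count, and a pose is by the table
when at least $P_\mathrm{subpose}$ subposes are.

**Metric.** Over any set $P$ of pose detections,
$F = \frac{1}{|P|}\sum_{p \in P} r(p)$ with $r(p) = 1$ for an
interacting pose. Because $F$ averages over detections, a missed person
simply does not contribute, and identity switches cancel out — the two
failure modes a geometric tracker in a crowded room cannot avoid. The
same form gives a movement fraction ($r(p) = 1$ when moving) and, from
interval annotations, a patient-interaction fraction (samples labelled
'absence' are excluded from $P$).

## Default parameters

| parameter | default | meaning |
|---|---|---|
| `f_motion` | 5 frames | displacement span |
| movement subposes | shoulders; head | arms legitimately move during table work; legs detect worst, so neither constrains movement |
| `M_keypoint` | 1 each | one still keypoint suffices per subpose |
| `tau_m` | 17.5 px | displacement threshold per 5 frames |
| `gamma_m` | 0.3 | movement confidence gate |
| `M_subpose` | 1 | shoulders-still OR head-still |
| position subposes | wrists (1 of 2), shoulders (1 of 2), head (2 of 5) | `P_keypoint` per subpose |
| `gamma_p` | 0.3 / 0.3 / 0.15 | facial keypoints are small and dim-light-sensitive, hence the lower head gate |
| `P_subpose` | 2 of 3 | combined position verdict |
| windows | 7500 frames, step 3750 | five minutes at 25 fps, half overlapped |

`interaction_params()` reproduces this operating point with no
arguments; every value can be overridden per subpose.

Boundary behaviour is pinned deliberately: *below a threshold* is strict
(`<`), so a displacement of exactly 17.5 px counts as moving and a
confidence of exactly 0.3 counts as reliable. The confidence gate reads
the current frame, not the earlier displacement endpoint. Displacement
is the net endpoint-to-endpoint distance, not a path sum — over five
frames the two are close for human motion, and the net reading keeps the
quantity well defined under intermittent detection. Thresholds are in
pixels per `f_motion` frames with no framerate normalisation; with
lighting-dependent framerates (roughly 6–26 fps in practice) the same
pixel threshold spans different wall-clock speeds, a known limitation
callers should keep in mind when comparing recordings.

## Tracking

The movement rule needs frame-to-frame correspondence, nothing more. The
tracker is therefore minimal: object keypoint similarity (OKS, Gaussian
falloff per keypoint with the standard COCO constants, object scale =
detected-keypoint bounding-box area) drives a two-stage greedy
association — high-confidence detections first, the remainder above a
low gate second, matches requiring OKS ≥ 0.3 — and a track unmatched on
a frame terminates. Tracklets shorter than two consecutive frames are
discarded. There is no motion model, no appearance feature and no track
re-birth: since $F$ discards identity, a broken track costs at most a few
assumed-still frames at the break. OKS averages over keypoints detected
in both poses (the intersection), 0 when the intersection is empty; ties
break by lower track id then detection index, making the tracker fully
deterministic. Defaults (high 0.6, low 0.1, OKS 0.3) are configurable.

## Geometry

Point-in-polygon uses the even-odd ray-crossing rule, boundary
inclusive. Regions are hand-drawn and loose, so boundary cases carry no
scientific meaning — but they must be deterministic, and the even-odd
rule stays well defined even for accidentally self-intersecting
polygons (accepted with a warning). The test suite checks the
implementation against `mgcv::in.out` on random points, where the two
conventions cannot differ.

## The synthetic generator

Real OR recordings cannot be published, so the generator stands in for
them in every test. It emulates exactly the features the classifier
reads and nothing more:

- actors as a fixed upright 17-keypoint stick figure (no articulation),
  scaled by shoulder width, following piecewise-linear waypoints, with
  declared still intervals held exactly;
- per-keypoint Gaussian jitter, independent dropout (elevated inside
  low-light intervals), and Beta-distributed confidences — dropped
  keypoints are written as undetected (confidence 0), low-confidence
  keypoints are generated by the confidence model, never conflated;
- spectators and a patient as role-tagged actors the rules treat like
  anyone else.

Ground truth is defined by running the rule set on the noise-free
scene — not by the scripts' intent flags, which are kept as metadata so
intent-vs-rule divergence (a cleaner standing still at the table fires
the rule) can be studied explicitly. Random draws are consumed in fixed
order and quantity regardless of the noise settings, so runs under one
seed are coupled: raising the dropout probability can only remove
detected keypoints. Passing tests on these scenes shows the pipeline
implements its own rules faithfully and degrades gracefully under
jitter/dropout; it does not show robustness to articulated motion,
crossing trajectories, or detector biases of real pose estimators.

The generator's recovery target is a design commitment: at zero noise
the measured $F$ equals scripted truth exactly; at jitter ≤ 2 px and
dropout ≤ 0.1 the mean absolute error over ten seeds stays within 0.02.
The bundled scenes use 2000–2400 frames and 1–4 actors — small enough
for a fast default test run, large enough that window and tracker logic
are exercised non-trivially.

## Numerical and degenerate-input choices

- Empty record sets raise an error rather than returning 0: $F$ divides
  by $|P|$, and 0/0 must not masquerade as "no interaction". Windows
  with no detections carry `NA` for the same reason.
- Windows are half-open `[start, start + length)`; every window whose
  start precedes the recording end is kept, so trailing windows may
  cover fewer frames rather than silently dropping the tail.
- Windows straddling a phase boundary are assigned by start frame — a
  simple deterministic convention; the per-phase fractions still
  recombine exactly to the global value when weighted by pose count.
- A pose whose detected-keypoint bounding box is degenerate (single
  visible keypoint) gets an OKS scale floored at 1 px² instead of a
  division by zero.
- The patient and spectators are classified like everyone else;
  filtering by role is left to the caller, since the detections carry no
  role information.

## Known limitations

Pixel thresholds are not framerate- or perspective-corrected; the
tracker cannot survive full occlusions; the rule measures a proxy
(still + positioned), not intent — annotated patient interaction is the
package's companion measurement for exactly that gap; and the synthetic
scenes, while statistically structured like the intended input, are not
real detector output.
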