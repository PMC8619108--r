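---
title: "Quantifying pig social contacts by tracking-by-detection"
author: "pigtrackr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pig social contacts by tracking-by-detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigtrackr)
```

## The problem and the method

Group-housed pigs are highly social; mixing unacquainted animals triggers
agonistic interactions (head-to-head confrontations, tail biting) that
matter for welfare and health monitoring. Manually scoring such encounters
from pen video is costly, so pigtrackr automates the chain from per-frame
keypoint detections to a table of social contacts and a weighted contact
network, for a *known, fixed* number of animals observed top-down.

The pipeline is classic tracking-by-detection:

1. **Detection / codec.** Each animal's pose in a frame is four keypoints —
   shoulder, tail, left ear, right ear. Poses are represented as a
   seven-channel binary image stack: a disc per keypoint channel and a
   rasterised segment per connection channel (shoulder–tail,
   shoulder–left-ear, shoulder–right-ear). The shoulder–tail *line channel*
   carries each animal's location: 8-connected components are found by a
   depth-first flood search, each component's two pixels of maximal
   pairwise distance are its endpoints, and the endpoint closer to a
   shoulder-channel blob is labelled shoulder (ear evidence breaks ties;
   with no evidence at all the pose is kept but flagged orientation-ambiguous).
   The body orientation is then `normalize(shoulder − tail)`.
2. **Tracking.** One constant-velocity Kalman filter per animal tracks the
   shoulder point. Per frame the filters predict, predictions are matched
   to detections one-to-one by minimising total Euclidean distance
   (Hungarian algorithm, gated), and matched filters update. A frame whose
   detection count differs from the known animal count is flagged
   *corrupted*: its detections are discarded and every filter is updated
   with its own previous estimate as the measurement, with the measurement
   variance inflated, so suspect input is down-weighted rather than
   trusted.
3. **Contacts.** Per frame, every animal receives a head circle and a tail
   circle of common radius `r = mean(shoulder–tail length) / alpha`
   (`alpha = 3` by default). Two animals are in *head–head* contact when
   their head circles intersect (centre distance at most `2r`, boundary
   inclusive) and in *head–tail* contact when one head circle intersects
   the other's tail circle (role-tagged; both directions are checked).
   Recomputing `r` each frame lets the regions adapt to animal size.
4. **Networks.** The per-frame contact rows aggregate into an undirected
   weighted graph: nodes are animal ids (isolated animals retained), edge
   weight is contact frequency, filterable by contact type. Because
   "frequency" can reasonably mean per-frame rows or discrete bouts, both
   units are offered (`unit = "frames"` is the default; `"episodes"`
   counts maximal runs merged across gaps of at most `gap_tolerance`
   frames, 5 frames = 0.5 s at 10 fps by default).

## Evaluation protocols

Two separate protocols mirror how such a system is scored.

**Detection.** Around every annotated shoulder point a circular *detection
region* is drawn whose radius is the frame's mean shoulder-to-ear
distance. Exactly one predicted point inside a region is a true positive;
extra points inside a region and points inside no region are false
positives; an empty region is a false negative — so `TP + FN` always equals
the number of annotated animals. Sensitivity `TP/(TP+FN)`, precision
`TP/(TP+FP)` and `F1 = 2TP/(2TP+FP+FN)` follow. When region assignment is
ambiguous (overlapping regions) a prediction goes to the nearest containing
region, ties to the lower truth index — a deterministic, conservative rule.

**Tracking.** `MOTA = 1 − (FP_T + FN_T + IDSW)/N`. The classifier matches
predicted track points to truth per frame within a localisation threshold
(by default the same detection-region radius, for symmetry): unmatched
truth is a false negative, unmatched prediction a false positive — a track
parked at an empty spot while its animal goes undetected counts as both.
Identity switches are detected against a truth-anchored mapping (each truth
id remembers its last matched predicted id) and counted once per change,
never per frame; two complementary changes in the same frame — the classic
case of two animals exchanging ids after an occlusion — are merged into a
single switch event, which is how such "cases" are conventionally counted.
`N` is the number of tracker-emitted points presented (overridable), i.e.
the detections the tracker consumed, not the number of true animals.

## The simulator: what it emulates, and what it does not

Because no public pen video ships with the package, a simulator provides
ground truth for every stage. It emulates the operating conditions the
method targets: a 640 × 400 px top-down view at 10 fps, a fixed known
number of pigs of body length 90 px (ear offset 18 px), waypoint-following
movement with at most `body_length/10` px displacement and 15° heading
change per frame — at 10 fps even brisk animal motion produces only slight
pixel shifts, which is the regime the constant-velocity filter assumes.
Scripted *approach events* steer a chosen pair together so that a requested
head–head or head–tail contact is realised inside a requested frame window;
realisability is guaranteed by construction (scripted pairs start within
closable distance and begin steering early), and the generated contact
table is, by definition, the frame-wise proximity-region rule applied to
the generated poses — the test suite checks it against an independent
brute-force oracle.

The corruption model reproduces the detector failure modes that matter
downstream: isotropic Gaussian keypoint jitter, per-pig-frame missed
detections, Poisson-distributed spurious full poses (full poses, so they
exercise the tracker, not just detection scoring), shoulder–tail swaps,
and occlusion episodes modelled as detection dropout.

What the simulator does *not* emulate: photo-realistic appearance, partial
occlusion geometry (occlusion is dropout, not overlap rendering), lying
clusters, animal growth within a sequence, or correlated detector errors.
Passing tests therefore demonstrate the correctness of the codec, tracker,
contact logic and metrics under the stated noise model — not detection
accuracy on real farm video, which depends on a trained detector and
annotated footage.

## The optional detector

The detector module reproduces the reference encoder–decoder topology: 25
convolutional layers (3 × 3, zero padding, stride 1, ReLU), four 2 × 2 max
poolings taking 640 × 400 input to a 40 × 25 latent map, six stacked
bottleneck convolutions, four upsampling stages each followed by a skip
concatenation from the encoder, and a sigmoid output layer producing the
seven channels; training uses Adam on binary cross-entropy with a seeded
90/10 train/validation split. Filter counts follow a doubling schedule
(`base_filters` 16 → 256 at the bottleneck) since only the layer/pool
structure is fixed by the design; the width is configurable, and the
desk-scale smoke run in `scripts/detector_smoke.R` uses a narrow width on
64 × 64 crops (200 crops, 30 epochs) so it finishes in minutes on one CPU.
The augmentation set — vertical shift, horizontal shift, shrink, rotation,
applied jointly to the image and all seven annotation channels — expands
`n` annotated frames into `5n` training pairs; magnitudes (±10% shift,
0.9 × shrink, ±15° rotation) are configurable since only the operation set
is fixed. The whole pipeline runs without this module: `decode_stack()`
accepts any channel stack, and `track_sequence()` accepts any detection
table.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `alpha` | 3 | — | Region scale; large enough to cover the head/tail area, small enough that passers-by do not fire events. Doubling `alpha` halves `r` and can only remove events. |
| `head_offset_frac` | 0 | fraction of `r` | Head circle centred on the shoulder keypoint; a forward offset along the orientation is available because the head lies ahead of the shoulder, but 0 is the conservative reading. |
| `marker_radius`, `line_width` | 4, 3 | px | Chosen so keypoint discs do not merge at typical inter-animal distances at 640 × 400. |
| `min_component_pixels` | 10 | px | Noise floor for line components; a genuine 90 px body line has hundreds of set pixels. |
| `gate_radius` | median body length of the initialisation frame | px | Association gate; one body length comfortably exceeds per-frame motion (9 px) plus filter transients. |
| `process_noise`, `base_measurement_noise` | 1, 4 | px²/frame², px² | Mild process noise and a few-pixel measurement noise fit the slight-motion regime; the filter then trusts clean detections heavily. |
| `inflation_factor` | 10 | — | Noise multiplier on corrupted-frame self-measurements (and on matched detections whose innovation exceeds `inflation_innovation × gate`). The mechanism is fixed; the magnitude is a package choice. |
| `gap_tolerance` | 5 | frames | 0.5 s at 10 fps; bridges single-frame flicker when merging episodes. |
| `threshold` | 0.5 | — | Binarisation of sigmoid detector outputs. |

## Numerical and degenerate-input choices

* Circle intersection is boundary-inclusive (`<= 2r`) so event sets are
  deterministic under exact arithmetic at the boundary.
* Line endpoints are the component's maximal-diameter pixel pair (computed
  via the convex hull); among tied pairs the first in hull order is taken
  and endpoints are ordered lexicographically, so extraction is
  deterministic.
* A saturated stack (everything above threshold) produces one giant
  component and decodes to at most one degenerate pose — never a crash.
  Merged line components of touching animals decode as a single
  (typically ambiguous) component; splitting them is out of scope, matching
  the known occlusion failure mode of this class of methods.
* Degenerate poses (shoulder = tail) are excluded from region construction
  with a warning; an all-degenerate frame yields an empty region set.
* Kalman updates use the Joseph-form covariance so extreme noise scales
  (the 1e±12 limiting tests) stay numerically stable; non-finite
  measurements are treated as missing.
* Fixed-cardinality tracking: tracks are born once, on the first frame
  containing exactly `n_pigs` detections (searched forward), and never die.
  If no such frame exists, initialisation fails loudly.
* The tracker matches detections against filter *predictions* (not the
  previous estimates); with per-frame motion this small the distinction is
  minor, but predictions are the principled choice.
* CSV writers render doubles at `%.17g`, so every artifact round-trips
  bit-exactly; reruns of the pipeline on the same input are byte-identical.

## What the test suite establishes

The suite is built on independent oracles: brute-force all-pairs region
intersection for contacts, label-propagation component labelling plus
exhaustive farthest-pair search for line extraction, exhaustive permutation
search for assignment optimality, closed forms for the Kalman limits and
the jitter model (the mean radial displacement of isotropic Gaussian jitter
is `sigma * sqrt(pi/2)`). At the reference operating conditions it checks,
among others: a ≥ 99% encode→decode round trip on isolated simulated poses
(200 frames × 8 pigs); zero identity switches and MOTA exactly 1.0 on
clean simulated detections (5 pigs, 500 frames); exact oracle equivalence
of contact detection on 1,000 random frames; and, with 10% missed
detections and staged crossings, a degraded MOTA in which identity
switches coincide with detection-failure windows — the qualitative
signature that switches follow missed detections rather than close-range
confusion. Problem sizes throughout were chosen so the full suite runs in
a couple of minutes on one CPU while keeping every estimate
well-conditioned.

## Known limitations

* No re-identification: identity is purely motion-based, so long occlusions
  of interacting animals can swap ids — by design, matching the method
  being reproduced.
* Variable group sizes (birth/death of tracks) are out of scope.
* The contact taxonomy is geometric (head–head, head–tail); it does not
  infer behaviour (nosing vs biting), and network analysis beyond graph
  construction (centrality, communities) is left to downstream tools.
* The detector is toy-scale by default; reproducing farm-video detection
  accuracy requires annotated footage and GPU-scale training, which the
  package does not attempt.
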