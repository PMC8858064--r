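---
title: "Annotating blink and head-movement EEG artifacts from facial landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating blink and head-movement EEG artifacts from facial landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earmark)
```

`earmark` turns a 68-point facial-landmark stream, synchronized with an EEG
recording, into 1-second-granularity artifact annotations: which seconds
contain a blink (per eye) and which contain a micro or distinct head
movement. This vignette is the package's own account of the method — the
model and its assumptions, the tunable parameters, what the synthetic
generator does and does not emulate, and the design decisions that were
genuinely open.

## The detection model

### Blinks

Eye openness is summarized per frame and per eye by the eye aspect ratio
(EAR): the two vertical eyelid distances summed, over twice the horizontal
eye-corner distance. It is a pure shape ratio — invariant to where the face
sits in the image, to distance from the camera and to in-plane rotation —
and collapses toward zero as the eye closes.

Fixed EAR cutoffs transfer poorly across subjects, lighting and eye shapes,
so the threshold is calibrated: the subject holds their eyes closed for
about a minute before the session, and the per-eye threshold is the *mean*
closed-eye EAR. The detector then flags a 1-second window when the window's
*minimum* EAR falls to or below the threshold — the minimum, not the mean,
because a 200–300 ms blink touches only a handful of frames in a 25-frame
window. The boundary is inclusive: a minimum exactly at the threshold
counts as a blink. Eyes are processed fully independently (left and right
thresholds and statuses), with a combined `blink_any` flag for convenience.

### Head movements

The pose estimate uses only three landmark-derived quantities, so it needs
no 3-D model, camera intrinsics, or depth:

* **Yaw.** The two eye centers (A, B) and the nose tip (E) span a roughly
  isosceles triangle. As the head turns about the vertical axis, the
  triangle's image-plane projection foreshortens the inter-ocular distance.
  With `AB` the calibrated frontal inter-ocular distance, `AC` the current
  projected one, and `theta` the in-image angle at A between the rays
  toward B and toward E, the turn angle `phi` satisfies

  `cos(phi) = AC * sin(theta) / sqrt(AB^2 - AC^2 * cos^2(theta))`.

  At the frontal pose (`AC = AB`) this is identically 1 for *any* `theta`,
  so the estimate is exactly zero there — an algebraic consistency check the
  unit tests assert. The lateral direction (left/right) is taken from the
  sign of the nose tip's horizontal offset from the eye-center midpoint.
* **Nod.** The distance `d` between the top of the nose bridge (point 27)
  and the nose tip (point 30) shrinks as the head pitches. With `D'` the
  calibrated median of `d` over a frontal minute, the nod angle is
  `|d - D'| / D' * 90` degrees, clamped into [0, 90]. The direction of the
  pitch is discarded.

Per 1-second window the frame angles average into `psi`, and the
second-to-second change `|psi_t - psi_{t-1}|` classifies the window:
static when at most 10 degrees, micro movement up to 30 degrees, distinct
beyond. Vertical and horizontal axes are classified separately and the
window's head status is the larger of the two. Differencing consecutive
windows, rather than thresholding the absolute pose, makes the detector
sensitive to *movement* — the thing that produces the EEG artifact — and
immune to a subject who simply sits slightly turned.

Key assumptions: the subject is seated at a fixed distance (semiconstrained
environment), so inter-ocular changes reflect rotation, not approach; the
calibration pose is genuinely frontal; and the upstream landmark detector
keeps tracking through the poses of interest. If the subject leans toward
the camera, `AC` can exceed `AB`; the arccos argument is then clamped and
yaw reads zero rather than propagating a complex number.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `fps` | 25 | frames/s | nominal landmark rate; calibration N = 60 x fps |
| window length | 1 | s | annotation granularity; also the psi averaging span |
| blink threshold | calibrated | EAR | per-eye mean closed-eye EAR |
| `nod_baseline_D` | calibrated | px | median frontal bridge-tip distance |
| `interocular_baseline_AB` | calibrated | px | frontal eye-center distance, fixed once |
| micro / distinct | 10 / 30 | degrees | head-movement class boundaries |
| report rounding | 2 | decimals | half-up, matching conventional tables |

The 10/30-degree boundaries and the 1-second window are the method's
published operating point; they are exposed in the configuration because
users may legitimately tune them, but the defaults are the validated ones.
Boundary conventions are inclusive on the left class: a change of exactly
10 degrees is static, exactly 30 degrees is micro.

## Windowing and synchronization

Windows are half-open intervals `[w, w+1)` aligned to the landmark stream's
first timestamp. Assignment is by timestamp, never by frame counting: if
the capture drops frames, the affected window is evaluated on the frames it
has (the blink minimum needs only one), a fully empty window yields `NA`
statuses, and later windows keep their positions. A trailing partial window
is still evaluated. The head-status differencing carries the last observed
window mean across empty gaps.

The EEG side shares the clock: events project onto samples by half-open
interval membership, and `downsample_to_windows()` brings a recording to
the camera's analysis rate by timestamp-block means, so non-integer rate
ratios are handled without resampling filters. Annotation is computed in
batch over the stream; in a live setting the same outputs would be
available one window after the fact (a window's status needs the window to
close, plus its predecessor's mean), a latency inherent to the differencing.

## The synthetic generator

Real validation data for this method is a person on video, which a package
cannot ship. The generator instead renders the *geometry* the detectors
consume, from a deterministic schematic face template (open-eye EAR exactly
0.3, inter-ocular 120 px, bridge-tip distance 60 px):

* **Blinks** scale the eyelid points toward the eye-center row by a depth
  fraction over the event span.
* **Nods** scale the bridge-tip distance by `1 - angle/90` — the exact
  inverse of the detector's nod model.
* **Yaw turns** shift the nose block laterally and compress the projected
  inter-ocular distance. The printed projection formula does not invert a
  naive image-plane compression when `theta` differs from 90 degrees, so
  the compression factor is solved numerically (a fixed-point iteration,
  converging to 1e-14 in a few steps) such that the detector's own formula
  recovers the scripted angle exactly. This is a deliberate choice: the
  generator probes the pipeline — calibration, windowing, differencing,
  classification, scoring — not a 3-D rendering model's disagreement with
  the projection formula.

Head events are *relative* rotations: each event turns the head by its
magnitude away from the currently held orientation, which is then held
until the next event on that axis. The magnitude is therefore exactly the
second-to-second change the classifier thresholds, so ground truth follows
from the 10/30 rule without simulation, and a turn-away followed by a
return reads naturally as two movement events. Directions are chosen
automatically to keep the held yaw small and the held nod within [0, 45]
degrees — beyond roughly 45 degrees of sustained pitch a 68-point landmark
detector loses the face, so streams with such poses would not exist; the
cap also keeps the nose tip clear of the inter-ocular line, where the yaw
formula is ill-conditioned (near that degenerate geometry, sub-pixel jitter
produces tens of degrees of yaw noise — a genuine limitation of the
trigonometric estimate, documented below).

Positional jitter is i.i.d. Gaussian per coordinate (default 0.5 px for
calibration segments, a typical landmark-localization error at webcam
resolution). Everything is a pure function of (script, seed).

The bundled `demo` preset scripts the 24-second demonstration scenario —
two both-eye blinks and two opposite-direction turns, one micro (20
degrees) and one distinct (40 degrees of relative change). The `random`
preset places events at integer onsets at least 2 s apart, with blink
depths in [0.95, 1] and head magnitudes fixed at the demonstration's
representative 20/40 degrees: accumulated holds from continuously drawn
magnitudes can land a true change within a degree of a class boundary,
where the classification is not meaningfully defined, and the recovery
properties this generator exists to test all presuppose magnitudes away
from the boundaries.

What the generator does **not** emulate — and what passing its tests
therefore does not show: landmark-detector failure modes that are
structured rather than i.i.d. (pose-dependent bias, tracking loss,
temporally correlated drift), eyelid occlusion during downward gaze,
eye-drooping (which this method cannot distinguish from blinks, a known
property), combined roll, translation toward the camera, and real EEG
physiology. The synthetic EEG is shape-level only: band-limited noise with
slow frontal deflections for blinks and broad low-frequency drift for head
movements, sufficient to test masking and downsampling, not a forward
model.

## Evaluation semantics

Each category is an independent binary per-second detection problem over a
session of `total` seconds: `detection` flagged seconds, of which `wrong`
are absent from the reference, and `miss` reference seconds not flagged.
Sensitivity and specificity follow as `TPR = TP/(TP+FN)` with
`TP = detection - wrong`, `FN = miss`, and `SPC = TN/(TN+FP)` with
`TN = total - detection - miss`, `FP = wrong` — each second counts as one
trial. Undefined ratios (no positive seconds, or no negative ones) are
reported as `NA`, never as 0. Reported percentages round half-up to two
decimals; exact fractions are carried alongside because half-up rounding at
the second decimal is itself a formatting convention, not arithmetic.

## Numerical choices

* Even-count medians are the mean of the two central order statistics.
* `acos` arguments are clamped into [-1, 1]; `AC > AB` (lean-in) clamps to
  the frontal reading rather than erroring mid-session.
* Ties at thresholds: blink boundary inclusive (min EAR equal to the
  threshold flags), head boundaries inclusive on the lower class.
* Window membership uses a 1e-9 guard when flooring timestamps so that
  frames placed exactly on a boundary by construction do not fall into the
  previous window through floating-point representation.
* The first window of a session has no predecessor and is static by
  convention.
* Degenerate geometry errors (zero eye span, coincident eye centers) name
  the offending frame; streams violating the 68-point invariant are
  rejected outright, never truncated.

## Design decisions that were genuinely open

* **Eye labels.** The EAR formula's "L" block (indices 36-41) is, in the
  standard 68-point scheme, the *subject's right* eye. The formula's labels
  are kept verbatim so every index in the code matches the published
  formulas; the documentation carries the warning.
* **Both detectors run every window.** The flow diagram's literal reading
  gates head-movement detection behind blink detection, which would make a
  head-only artifact undetectable — contradicting the published evaluation,
  which scores the categories independently. Blink and head detection
  therefore run unconditionally and a window may carry both flags.
* **Per-eye thresholds.** The calibration formula is written with a single
  threshold but the published pseudocode keeps separate left/right values;
  the separate values are used.
* **Window alignment** to the stream start (not wall-clock seconds), since
  nothing in the method depends on absolute time.
* **Calibration length** accepts anything from 1 s up, warning below the
  nominal 60 s — full-minute fixtures at every test site would buy
  precision the tests do not need.
* **Yaw sign convention.** The published description reads the lateral
  direction "according to point A's coordinates" without defining the rule;
  the committed interpretation is the sign of the nose tip's offset from
  the eye-center midpoint, which an x-mirror test pins down.

## Problem sizes

The shipped tests run on desk-scale data chosen to exercise every code
path: calibration segments of 5-60 s (125-1500 frames), scenes of 3-120 s
at 25 fps, EEG at 100-250 Hz, 1000-tuple property sweeps for the metric
identities. The full suite and the reproduction script each complete in
well under a minute on a single core.

## Known limitations

* Yaw geometry degenerates when the nose tip approaches the inter-ocular
  line (extreme pitch): the estimate becomes noise-dominated there. Real
  sessions do not reach that pose while landmarks are still tracked.
* Blinks and eye-drooping are indistinguishable by design; both contaminate
  the EEG similarly, so for artifact annotation the conflation is benign.
* No roll estimation, no translation compensation beyond the lean-in clamp,
  no sub-second onsets (1-second granularity throughout).
* Artifact *removal* is out of scope: the output marks seconds for
  downstream cleaning or exclusion, it does not modify the EEG.
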