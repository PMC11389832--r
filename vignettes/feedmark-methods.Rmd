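---
title: "Quantifying insect feeding behavior from time-lapse leaf scans: methods and design notes"
author: "feedmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{feedmark methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feedmark)
```

## The measurement problem

Lepidopteran larvae feed on leaves in discrete bouts separated by rest. A
flatbed scanner photographing caged leaves once per minute turns that
behavior into a time series: the leaf area shrinks stepwise, each step a
feeding event. feedmark turns such an image stack into per-event behavioral
parameters (area consumed, duration, feeding rate, inter-event interval),
per-assay summaries, genotype contrasts, and a spatial map of where each
bite was taken.

Two obstacles make this more than thresholding and counting:

1. **The larva can look like the leaf.** A green caterpillar sitting on the
   background, or on a hole it just ate, is counted as leaf by any color
   threshold.
2. **The larva can look like nothing.** A dark caterpillar on a dark
   (reflective-mode) background is invisible to the threshold, so it
   punches a transient hole in the leaf mask wherever it rests.

## Segmentation model

### mask1: color thresholding

Each frame is thresholded per pixel: foreground iff every constrained
channel lies in its inclusive range (`color_threshold()`, ranges in
`[0, 1]`, HSV via `grDevices::rgb2hsv`, hue treated circularly). Two
presets mirror the two scanning set-ups:

* `reflective` — green hue window (`h` in [0.16, 0.50]) with minimum
  saturation 0.25 and value 0.15, for colored leaves on a blacked-out
  background;
* `transmissive` — value at most 0.5, for back-lit scans where leaf and
  larva are both dark silhouettes on white. This is the set-up of choice
  for dark-bodied larvae, which the reflective threshold cannot see.

No published channel ranges exist for this assay, so the preset numbers are
package defaults chosen on the synthetic scenes; they are expected to be
overridden per dataset (config `threshold_spec`, or a `threshold_spec()`
argument). No morphological cleanup is applied by default — an optional
minimum-component-size filter exists (`min_component_px`) but is off,
because the pipeline's robustness mechanism is the next stage, not
despeckling.

### mask2: cumulative time-difference masking

`cumulative_mask()` applies, frame by frame,

$$\mathrm{mask2}(1) = \mathrm{mask1}(1), \qquad
  \mathrm{mask2}(t+1) = \mathrm{mask1}(t+1) \wedge \mathrm{mask2}(t),$$

i.e. every pixel that is background once stays background. The biological
assumption is monotone consumption: a consumed leaf pixel never returns
within an assay. Under that assumption mask2 is immune to obstacle 1
above: when a leaf-colored larva crosses ground that was already consumed,
those pixels are already background in mask2 and stay there.

Two consequences are properties of the algorithm, not bugs, and are
deliberately not "repaired":

* A pixel that flickers to background for a single frame (sensor noise) is
  deleted permanently. Mitigation is threshold choice (wide, robust
  ranges), not temporal filtering.
* A dark larva in reflective mode (obstacle 2) makes mask2 permanently
  delete every leaf pixel it ever rests on. That failure mode is real and
  is why transmissive scanning exists; the synthetic generator reproduces
  it (`larva_palette = "dark_patterned"`).

Masking runs on full frames; rectangular per-cage ROIs only restrict the
area measurement (`measure_roi_areas()`), with
`area_mm2 = pixels × calibration²` and calibration `25.4/dpi` mm per pixel.

## Event model

For the per-ROI area series $S(t)$ the loss rate is
$D(t) = -(S(t+1) - S(t))/\Delta$ with $\Delta$ the frame interval in
minutes (`diff_series()`), so units are mm² min⁻¹ at any cadence. A feeding
event is a maximal run of consecutive points with $D(t)$ *strictly* above
the threshold (default 0.2 mm² min⁻¹). "Exceeds" is read as strict;
ties at exactly the threshold are measure-zero in real data, so no
configuration knob is offered for the comparison itself. Whether a single
above-threshold point suffices is not standardised, so the minimum run
length is exposed (`min_run`, default 1 frame).

Per event: area = $\sum D(t)\,\Delta$ over the run (the integrated peak),
duration = run length × $\Delta$ (the peak width), rate = area/duration.
The identity rate × duration = area holds to floating tolerance by
construction and is asserted in the tests.

**Frame-index convention.** Events are reported in derivative indices:
$D(t)$ is the loss *between* mask frames $t$ and $t+1$. Consequently the
mark of an event with run $[s, e]$ is
`mask2[s] & !mask2[e + 1]` — the difference between the mask one frame
before the loss becomes visible and the mask of the last frame of the
event — which by mask2 monotonicity is exactly the set of pixels lost
during the event.

**Intervals.** The interval after an event is
`(start_frame[next] − end_frame[this]) × Δ` minutes. The end-to-start
wording leaves an off-by-one open; under this convention two runs
separated by $g$ quiet minutes report $g + \Delta$. The synthetic truth
uses the same stated convention, and the tests verify that scripted gaps
are reconstructed under it. Intervals above 100 min are flagged
(`interval_excluded`) — they usually reflect molting — and are omitted
from interval summaries only; the flanking events keep contributing to
duration/area/rate.

**Per-assay summaries and contrasts.** An assay is summarised by the
median of each parameter over events *starting* within the analysis window
(default 999 min; start time is used because the selection rule's
reference point is not standardised and start is the natural anchor for an
event-initiation window). Medians over an even count use the midpoint.
Genotype comparisons (`compare_groups()`) run Welch's unequal-variance
t-test with Welch–Satterthwaite degrees of freedom on the per-assay
medians, reporting group mean ± sample SD. Manual quality control —
dropping cages with leaf movement or feces artifacts — is a user-supplied
exclusion list (`exclude_rois`), never automated.

## Spatial model

The mark mask of each event (above) yields its center of gravity as the
unweighted mean of foreground pixel coordinates (0-based; "center of
gravity" of a uniform region, no intensity weighting), and consecutive
marks give Euclidean distances in mm. Millimetre coordinates originate at
the ROI's top-left corner (x along columns, y along rows), as documented in
the marks CSV. Overlays use the first mask frame as the reference: leaf
black, current mark magenta, earlier marks cyan, background white. Marks
are computed per ROI independently and are pixel-disjoint by mask2
monotonicity.

## The synthetic generator

`simulate_area_series()` produces an area series directly: initial area
minus piecewise-linear scripted consumption plus i.i.d. Gaussian noise.
`render_sequence()` produces the images themselves: an elliptical leaf
whose pixels are removed nearest-site-first around each event's feeding
site (pixel-quantized, so per-event mark areas are exact to one pixel and
marks are connected, compact regions), an elliptical larva moving along a
scripted path in either a leaf-like or a dark palette, per-pixel Gaussian
color noise, and 8-bit quantization. Both are bit-reproducible given the
script's seed, and both return the exact ground truth (per-frame masks and
areas, per-event parameters, mark masks and centroids) that the test suite
uses as its oracle.

What the generator emulates: stepwise monotone area loss, intermittent
bouts with molting-scale gaps, the leaf-colored-larva and
dark-larva-on-dark-background failure modes, reflective and transmissive
contrast, sensor noise. What it does not: leaf texture and veins, specular
highlights, JPEG artifacts, leaf movement or wilting, feces, larva growth.
Passing the simulation suite therefore demonstrates the algorithms are
correct under the stated assumptions — it does not by itself validate
threshold presets on any particular scanner, which is why the presets are
user-overridable.

Default study conditions used in the validation suite: 50 simulated assays
of 8–15 events each, rates 0.3–1.5 mm² min⁻¹, durations 2–10 min, gaps
5–60 min, area noise SD 0.02 mm², detection threshold 0.2 mm² min⁻¹, 1-min
frames; rendered stacks of 30–45 frames at 120×160 px and 0.2 mm px⁻¹
(127 dpi) with larva radii 3×5 px and color noise SD 0.005–0.01. These
sizes keep each rendered scene comfortably larger than the larva and each
event's mark while remaining quick to generate.

## Numerical choices and degenerate inputs

* Strictly-greater threshold comparison (see above); detector is monotone
  in the threshold (more threshold, never more event-frames).
* Zero detected events is a valid result everywhere: summaries carry
  `n_events = 0` with `NA` medians (flagged, not dropped); the events CSV
  is header-only.
* An event whose loss fell entirely outside a ROI yields an empty mark:
  the event is excluded from that ROI's spatial table with a warning.
* Frame serial gaps are allowed (skipped scans) and treated as consecutive
  frames at the nominal interval, with a warning.
* ROI bounds are validated at use time against the frame they are applied
  to, naming the offending label.
* Group comparisons require at least two assays with defined medians per
  group; fewer is an explicit error.
* All randomness is seeded through the scripts' `seed` fields; the
  pipeline itself is deterministic, and repeated runs produce
  byte-identical CSVs.

## A worked example

```{r example, eval = FALSE}
scene <- scene_spec(scan_mode = "reflective", noise_sd = 0.005)
script <- random_behavior_script(n_events = 10, scene = scene, seed = 1)
stack <- render_sequence(script, scene, dir = "stack")

frames <- read_frame_sequence("stack", "frame_*.png", mm_per_px = 0.2)
mask2 <- cumulative_mask(color_threshold(frames))
areas <- measure_roi_areas(mask2, rect_roi("cage1", 0, 0, 120, 160))
events <- compute_intervals(detect_events(diff_series(areas$cage1)))
summarize_assay(events)
marks <- extract_marks(mask2, events, rect_roi("cage1", 0, 0, 120, 160))
render_position_plot(marks)
```

## Known limitations

* No behavior classification beyond feeding events (no resting-position
  tracking, no molting detection beyond the interval cutoff).
* The monotone-consumption assumption fails for moving or wilting leaves;
  such cages must be excluded via the manual QC list, as in the original
  protocol.
* Only rectangular ROIs are supported.
* The single-frame-flicker deletion property of cumulative masking means
  very noisy thresholds bias areas downward; choose generous ranges.
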