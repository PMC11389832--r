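# feedmark

Quantification of insect feeding behavior from time-lapse images of leaves.

Herbivory bioassays are usually scored by endpoint leaf area, which hides
*how* the insect fed. When a flatbed scanner photographs caged leaves once a
minute, the leaf-area time series S(t) of each cage encodes the full
behavioral structure: discrete feeding bouts, their speed, and the pauses
between them. feedmark implements the complete analysis chain for such
stacks, for researchers studying plant defense (e.g. trichome effects on
lepidopteran larvae) or insect feeding behavior generally:

1. **Segmentation** — per-frame color thresholding (`mask1`), then
   *cumulative time-difference masking* (`mask2`):

   mask2(1) = mask1(1),  mask2(t+1) = mask1(t+1) ∧ mask2(t)

   Once a pixel is background it stays background. Under the
   monotone-consumption assumption (eaten leaf never returns) this removes
   the classic artifact of a leaf-colored larva being counted as leaf.
2. **Event detection** — the loss rate D(t) = −ΔS(t)/Δt (mm² min⁻¹) is
   scanned for maximal runs of consecutive points strictly above a
   threshold (default 0.2 mm² min⁻¹). Each run is one feeding event with
   area consumed (∑D·Δt), duration (run length), rate (area/duration), and
   interval to the next event; intervals > 100 min (molting) are excluded
   from interval statistics.
3. **Summaries and contrasts** — per-assay medians over a 999-min window,
   compared between groups with Welch's t-test (Welch–Satterthwaite df) on
   the per-assay medians.
4. **Feeding-mark mapping** — per-event consumed regions
   (mask2 differencing), centers of gravity, Euclidean distances between
   consecutive marks, and overlay/summary figures.
5. **Synthetic ground truth** — a scripted generator renders time-lapse
   stacks (reflective or transmissive scenes, leaf-like or dark larva)
   with exact per-frame masks and per-event truth, so every stage is
   testable without real scans.

See `vignettes/feedmark-methods.Rmd` for the model, conventions and design
decisions.

## Worked example

```r
library(feedmark)

# A synthetic assay: 2 scripted feeding events, green larva, reflective scene
scene  <- scene_spec(width = 120, height = 90, mm_per_px = 0.2, noise_sd = 0.005)
script <- behavior_script(data.frame(
  start_min = c(3, 15), duration_min = c(4, 5), rate_mm2_per_min = c(0.8, 0.5),
  site_row = c(40, 50), site_col = c(50, 70)), seed = 7)
render_sequence(script, scene, n_frames = 30, dir = "stack")

# The pipeline
frames <- read_frame_sequence("stack", "frame_*.png", mm_per_px = 0.2)
mask2  <- cumulative_mask(color_threshold(frames))
roi    <- rect_roi("cage1", 0, 0, 90, 120)
areas  <- measure_roi_areas(mask2, roi)
events <- compute_intervals(detect_events(diff_series(areas$cage1)))
events
#> feeding_events: 2 event(s) in ROI 'cage1'
#>  event_id start_frame end_frame duration_min area_mm2 rate_mm2_per_min
#>         1           4         7            4     3.20            0.800
#>         2          16        20            5     2.48            0.496
#>  interval_to_next_min interval_excluded
#>                     9             FALSE
#>                    NA                NA

marks <- extract_marks(mask2, events, roi)
marks_table(marks)[, c("event_id", "centroid_x_mm", "centroid_y_mm", "dist_from_prev_mm")]
#>   event_id centroid_x_mm centroid_y_mm dist_from_prev_mm
#> 1        1        9.9875      8.000000                NA
#> 2        2       13.9871      9.993548          4.468894
```

The two detected events recover the scripted parameters exactly (0.8 and
0.5 mm² min⁻¹ for 4 and 5 min; areas 3.2 and 2.5 mm² to one-pixel
quantization), and the second feeding mark formed 4.5 mm from the first.

A command-line driver wraps the same functions
(`exec/feedmark`, subcommands `simulate`, `segment`, `measure`, `detect`,
`marks`, `compare`, `run`), driven by a YAML config:

```sh
Rscript exec/feedmark simulate --out stack --seed 3
Rscript exec/feedmark run --config cfg.yaml
```

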