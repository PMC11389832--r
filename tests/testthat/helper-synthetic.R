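# Shared synthetic fixtures: small scenes and scripts that run in well under
# a second each. All geometry is 0-based to match the package's coordinate
# convention.

tiny_scene <- function(noise_sd = 0, scan_mode = "reflective",
                       larva_palette = "leaf_like") {
  scene_spec(width = 120, height = 90, mm_per_px = 0.2,
             scan_mode = scan_mode, larva_palette = larva_palette,
             larva_radii = c(3, 5), noise_sd = noise_sd)
}

two_event_script <- function(seed = 7) {
  behavior_script(
    data.frame(start_min = c(3, 15), duration_min = c(4, 5),
               rate_mm2_per_min = c(0.8, 0.5),
               site_row = c(40, 50), site_col = c(50, 70)),
    seed = seed)
}

# Straight-line larva path over n frames (rows are recycled downstream).
line_path <- function(from, to, n, visible = TRUE) {
  data.frame(row = round(seq(from[1], to[1], length.out = n)),
             col = round(seq(from[2], to[2], length.out = n)),
             visible = visible)
}

# Closed-form Welch statistic, independent of stats::t.test.
welch_oracle <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (length(a)^2 * (length(a) - 1)) +
                   vb^2 / (length(b)^2 * (length(b) - 1)))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Match detected events to truth events by frame-range overlap.
match_events <- function(truth, detected) {
  vapply(seq_len(nrow(truth)), function(i) {
    hit <- which(detected$start_frame <= truth$end_frame[i] &
                   detected$end_frame >= truth$start_frame[i])
    if (length(hit)) sum(detected$area_mm2[hit]) else NA_real_
  }, 0)
}

write_tiny_stack <- function(dir, noise_sd = 0, seed = 7) {
  render_sequence(two_event_script(seed), tiny_scene(noise_sd),
                  n_frames = 30, dir = dir)
}
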