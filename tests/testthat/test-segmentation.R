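make_series <- function(frames, cal = 0.2) {
  structure(list(frames = frames, serial = seq_along(frames), files = NULL,
                 frame_interval = 1, calibration = cal,
                 scan_mode = "reflective"),
            class = "frame_series")
}

test_that("a uniform in-range frame thresholds to all-foreground", {
  img <- array(rep(c(0.2, 0.6, 0.2), each = 20), c(4, 5, 3))  # green-ish
  fs <- make_series(list(img, img))
  m <- color_threshold(fs, threshold_preset("reflective"))
  expect_true(all(m$masks[[1]]))
  expect_equal(m$stage, "mask1")
})

test_that("HSV specs on grayscale input are a configuration error", {
  fs <- make_series(list(matrix(0.5, 4, 4), matrix(0.5, 4, 4)))
  expect_error(color_threshold(fs, threshold_preset("reflective")),
               "grayscale")
  # RGB spec treats gray as r=g=b and works
  m <- color_threshold(fs, threshold_spec("RGB", r = c(0.4, 0.6)))
  expect_true(all(m$masks[[1]]))
})

test_that("threshold_spec validates ranges and supports circular hue", {
  expect_error(threshold_spec("RGB", r = c(0.9, 0.1)), "min > max")
  expect_error(threshold_spec("HSV"), "at least one channel")
  expect_error(threshold_spec("HSV", q = c(0, 1)), "unknown channel")
  # wrap-around hue window selects reds on both sides of 0
  red1 <- array(rep(c(1, 0.05, 0.05), each = 1), c(1, 1, 3))
  fs <- make_series(list(red1, red1))
  m <- color_threshold(fs, threshold_spec("HSV", h = c(0.9, 0.1)))
  expect_true(m$masks[[1]][1, 1])
  m2 <- color_threshold(fs, threshold_spec("HSV", h = c(0.2, 0.8)))
  expect_false(m2$masks[[1]][1, 1])
})

test_that("reflective preset recovers leaf-plus-larva ground truth (mask1)", {
  scene <- tiny_scene(noise_sd = 0)
  n <- 12
  path <- line_path(c(45, 20), c(45, 100), n)
  script <- behavior_script(
    data.frame(start_min = 3, duration_min = 4, rate_mm2_per_min = 0.8,
               site_row = 40, site_col = 50),
    larva_path = path, seed = 1)
  r <- render_sequence(script, scene, n_frames = n)
  m1 <- color_threshold(r$frames)
  for (t in c(1, 6, n)) {
    larva <- feedmark:::ellipse_mask(scene$height, scene$width,
                                     c(path$row[t], path$col[t]),
                                     scene$larva_radii)
    expect_identical(m1$masks[[t]], r$truth$remaining_masks[[t]] | larva)
  }
})

test_that("transmissive preset captures both dark leaf and dark larva", {
  scene <- tiny_scene(noise_sd = 0, scan_mode = "transmissive",
                      larva_palette = "dark_patterned")
  path <- line_path(c(20, 20), c(20, 20), 8)  # parked on background
  script <- behavior_script(
    data.frame(start_min = 2, duration_min = 2, rate_mm2_per_min = 0.5,
               site_row = 45, site_col = 60),
    larva_path = path, seed = 1)
  r <- render_sequence(script, scene, n_frames = 8)
  m1 <- color_threshold(r$frames)
  larva <- feedmark:::ellipse_mask(scene$height, scene$width, c(20, 20),
                                   scene$larva_radii)
  expect_identical(m1$masks[[1]], r$truth$remaining_masks[[1]] | larva)
})

test_that("cumulative masking: constant input is a fixed point", {
  m <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  ms <- mask_series(rep(list(m), 5), "mask1")
  m2 <- cumulative_mask(ms)
  expect_identical(m2$masks, ms$masks)
  expect_equal(m2$stage, "mask2")
})

test_that("once background, never foreground again", {
  pix <- c(TRUE, FALSE, TRUE, TRUE)
  masks <- lapply(pix, function(p) matrix(p, 1, 1))
  m2 <- cumulative_mask(mask_series(masks, "mask1"))
  expect_equal(vapply(m2$masks, function(m) m[1, 1], TRUE),
               c(TRUE, FALSE, FALSE, FALSE))
})

test_that("a leaf-colored larva crossing consumed ground fools mask1 but not mask2", {
  scene <- tiny_scene(noise_sd = 0)
  n <- 30
  # larva starts on the leaf, then crosses the region consumed by event 1
  path <- rbind(line_path(c(55, 60), c(55, 60), 14),
                line_path(c(55, 60), c(40, 50), 6),
                line_path(c(40, 50), c(40, 120 - 8), 10))
  script <- behavior_script(
    data.frame(start_min = c(2, 20), duration_min = c(6, 4),
               rate_mm2_per_min = c(1.2, 0.6),
               site_row = c(40, 55), site_col = c(50, 75)),
    larva_path = path, seed = 2)
  r <- render_sequence(script, scene, n_frames = n)
  m1 <- color_threshold(r$frames)
  m2 <- cumulative_mask(m1)
  a1 <- vapply(m1$masks, sum, 0L)
  a2 <- vapply(m2$masks, sum, 0L)
  # mask2 tracks the truth everywhere; mask1 overestimates while the larva
  # sits on consumed ground or background
  expect_equal(a2, r$truth$area_px)
  expect_gt(max(a1 - r$truth$area_px), 0)
  # mask1 series is not monotone; mask2 is
  expect_true(all(diff(a2) <= 0))
})

test_that("mask2 is nested over time and contained in mask1 (random stacks)", {
  for (seed in 1:3) {
    scene <- tiny_scene(noise_sd = 0.01)
    script <- random_behavior_script(n_events = 3, first_start = 2,
                                     gap_range = c(3, 6), scene = scene,
                                     seed = seed)
    r <- render_sequence(script, scene)
    m1 <- color_threshold(r$frames)
    m2 <- cumulative_mask(m1)
    for (t in seq_len(length(m2) - 1)) {
      expect_true(all(m2$masks[[t + 1]] <= m2$masks[[t]]))
      expect_true(all(m2$masks[[t]] <= m1$masks[[t]]))
      expect_identical(m2$masks[[t + 1]], m1$masks[[t + 1]] & m2$masks[[t]])
    }
  }
})

test_that("with no insect and no noise, mask1 = mask2 = ground truth", {
  scene <- tiny_scene(noise_sd = 0)
  r <- render_sequence(two_event_script(), scene, n_frames = 25)
  m1 <- color_threshold(r$frames)
  m2 <- cumulative_mask(m1)
  expect_identical(m1$masks, r$truth$remaining_masks)
  expect_identical(m2$masks, r$truth$remaining_masks)
})

test_that("ROI measurement converts pixel counts with calibration squared", {
  masks <- rep(list(matrix(TRUE, 20, 20)), 3)
  ms <- mask_series(masks, "mask2", calibration = 0.1)
  a <- measure_roi_areas(ms, rect_roi("box", 5, 5, 10, 10))
  expect_equal(a$box$area_px, rep(100, 3))
  expect_equal(a$box$area_mm2, rep(1.0, 3))
})

test_that("disjoint ROIs partition their own counts without cross-talk", {
  m <- matrix(FALSE, 30, 30)
  m[1:10, 1:10] <- TRUE     # 100 px in ROI A only
  m[21:28, 21:26] <- TRUE   # 48 px in ROI B only
  ms <- mask_series(list(m, m), "mask2", calibration = 1)
  a <- measure_roi_areas(ms, list(rect_roi("A", 0, 0, 15, 15),
                                  rect_roi("B", 15, 15, 15, 15)))
  expect_equal(a$A$area_px, c(100, 100))
  expect_equal(a$B$area_px, c(48, 48))
})

test_that("out-of-bounds ROIs fail at measurement naming the label", {
  ms <- mask_series(list(matrix(TRUE, 10, 10)), "mask2")
  expect_error(measure_roi_areas(ms, rect_roi("toolarge", 5, 5, 10, 10)),
               "toolarge")
})

test_that("measured area tracks continuous truth within pixel quantization", {
  scene <- tiny_scene(noise_sd = 0)
  script <- two_event_script()
  r <- render_sequence(script, scene, n_frames = 25)
  m2 <- cumulative_mask(color_threshold(r$frames))
  a <- measure_roi_areas(m2, rect_roi("all", 0, 0, 90, 120))$all
  minutes <- a$minutes
  cont <- sum(r$truth$leaf_mask) * scene$mm_per_px^2 -
    feedmark:::cumulative_consumption(script$events, minutes)
  # each event adds at most one pixel of rounding per frame
  expect_true(all(abs(a$area_mm2 - cont) <= 2 * scene$mm_per_px^2 + 1e-9))
})

test_that("optional component-size filter removes speckle but is off by default", {
  img <- array(0.05, c(12, 12, 3))
  img[4:9, 4:9, ] <- rep(c(0.2, 0.6, 0.2), each = 36)  # 36-px leaf block
  img[1, 1, ] <- c(0.2, 0.6, 0.2)                      # 1-px speckle
  fs <- make_series(list(img, img))
  m_raw <- color_threshold(fs)
  expect_true(m_raw$masks[[1]][1, 1])
  m_filt <- color_threshold(fs, min_component_px = 4)
  expect_false(m_filt$masks[[1]][1, 1])
  expect_equal(sum(m_filt$masks[[1]]), 36)
})
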