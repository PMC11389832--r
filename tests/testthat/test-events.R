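test_that("the loss-rate series is the negative forward difference per minute", {
  expect_equal(diff_series(c(10, 10, 10))$loss_mm2_per_min, c(0, 0))
  d <- diff_series(c(10, 9.5, 9.5))
  expect_equal(d$loss_mm2_per_min, c(0.5, 0))
  expect_equal(d$frame, 1:2)
  # telescoping: the losses sum to total area change
  set.seed(1)
  s <- cumsum(rnorm(50))
  expect_equal(sum(diff_series(s)$loss_mm2_per_min), s[1] - s[50])
  # cadence scaling: rates are per minute, not per frame
  d2 <- diff_series(c(10, 9), frame_interval = 2)
  expect_equal(d2$loss_mm2_per_min, 0.5)
  expect_error(diff_series(10), "at least 2")
})

test_that("events are maximal above-threshold runs with integrated area", {
  ev <- detect_events(c(0, 0.5, 0.6, 0, 0.05, 0), threshold = 0.2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_frame, 2L)
  expect_equal(ev$end_frame, 3L)
  expect_equal(ev$duration_min, 2)
  expect_equal(ev$area_mm2, 1.1)
  expect_equal(ev$rate_mm2_per_min, 0.55)

  expect_equal(nrow(detect_events(rep(0, 10))), 0)

  two <- detect_events(c(0.3, 0, 0.3), threshold = 0.2)
  expect_equal(nrow(two), 2)
  expect_equal(two$duration_min, c(1, 1))
})

test_that("'exceed' is strict: values exactly at the threshold do not trigger", {
  expect_equal(nrow(detect_events(c(0.2, 0.2, 0.2), threshold = 0.2)), 0)
  expect_equal(nrow(detect_events(c(0.2, 0.2000001), threshold = 0.2)), 1)
})

test_that("min_run suppresses short runs", {
  d <- c(0.3, 0, 0.3, 0.4, 0)
  expect_equal(nrow(detect_events(d, min_run = 1)), 2)
  ev <- detect_events(d, min_run = 2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_frame, 3L)
})

test_that("raising the threshold never increases detected event-frames", {
  set.seed(11)
  d <- pmax(rnorm(300, 0.1, 0.2), 0)
  frames_at <- function(thr) {
    ev <- detect_events(d, threshold = thr)
    sum(ev$end_frame - ev$start_frame + 1)
  }
  thr <- seq(0.05, 0.8, by = 0.05)
  counts <- vapply(thr, frames_at, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("rate x duration equals area to floating tolerance", {
  set.seed(5)
  d <- pmax(rnorm(500, 0.15, 0.25), 0)
  ev <- detect_events(d, threshold = 0.2, frame_interval = 1)
  expect_gt(nrow(ev), 5)
  expect_equal(ev$rate_mm2_per_min * ev$duration_min, ev$area_mm2,
               tolerance = 1e-9)
  # conservation: events capture at most the total loss
  s <- 100 - cumsum(c(0, d))
  expect_lte(sum(ev$area_mm2), s[1] - s[length(s)] + 1e-12)
})

test_that("intervals follow the start-minus-end convention and the 100-min cutoff", {
  # schedule: A ends frame 10, B starts frame 25, C starts frame 180
  d <- numeric(200)
  d[9:10] <- 0.5
  d[25:27] <- 0.4
  d[180] <- 0.9
  evs <- compute_intervals(detect_events(d, threshold = 0.2))
  expect_equal(evs$interval_to_next_min, c(15, 153, NA))
  expect_equal(evs$interval_excluded, c(FALSE, TRUE, NA))

  single <- compute_intervals(detect_events(c(0, 0.5, 0)))
  expect_equal(nrow(single), 1)
  expect_true(is.na(single$interval_to_next_min))
})

test_that("per-assay summaries take medians over the analysis window", {
  d <- numeric(1500)
  d[11:12] <- 0.5    # duration 2, start minute 10
  d[31:34] <- 0.5    # duration 4
  d[61:70] <- 0.5    # duration 10
  d[1301:1302] <- 2  # starts after the 999-min window
  ev <- compute_intervals(detect_events(d, threshold = 0.2))
  s <- summarize_assay(ev, window = 999)
  expect_equal(s$n_events, 3)
  expect_equal(s$duration_min, 4)       # odd count: middle value
  ev2 <- compute_intervals(detect_events(d[1:60], threshold = 0.2))
  s2 <- summarize_assay(ev2)
  expect_equal(s2$duration_min, 3)      # even count: midpoint convention

  none <- summarize_assay(detect_events(rep(0, 10)))
  expect_equal(none$n_events, 0)
  expect_true(is.na(none$rate_mm2_per_min))
})

test_that("excluded intervals are left out of the interval median only", {
  d <- numeric(400)
  d[10] <- 0.5; d[20] <- 0.5; d[300] <- 0.5  # gaps: 10 and 280 frames
  ev <- compute_intervals(detect_events(d, threshold = 0.2))
  s <- summarize_assay(ev)
  expect_equal(s$interval_min, 10)   # the 280-min gap is excluded
  expect_equal(s$n_events, 3)        # but all events still count elsewhere
})

test_that("Welch comparison matches the closed-form oracle", {
  cmp <- compare_groups(1:5, 2:6, parameter = "rate_mm2_per_min")
  oracle <- welch_oracle(1:5, 2:6)
  expect_equal(cmp$t, oracle$t)
  expect_equal(cmp$df, oracle$df)
  expect_equal(cmp$p, oracle$p)
  # by hand: means 3 and 4, both variances 2.5, se = sqrt(2.5/5 + 2.5/5) = 1
  expect_equal(cmp$t, -1)
  expect_equal(cmp$df, 8)

  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  swapped <- compare_groups(2:6, 1:5)
  expect_equal(swapped$t, -cmp$t)
  expect_equal(swapped$p, cmp$p)

  expect_error(compare_groups(1, 1:5), "2 assays")
})

test_that("compare_groups pulls the requested parameter from assay summaries", {
  mk <- function(rate) {
    d <- c(rep(rate + 0.3, 3), rep(0, 5))
    summarize_assay(compute_intervals(detect_events(d, threshold = 0.2)))
  }
  a <- lapply(c(0.2, 0.3, 0.4), mk)
  b <- lapply(c(0.8, 0.9, 1.0), mk)
  cmp <- compare_groups(a, b, parameter = "rate_mm2_per_min")
  expect_lt(cmp$mean_a, cmp$mean_b)
  expect_lt(cmp$p, 0.05)
})

test_that("noise-free synthetic schedules are recovered exactly", {
  script <- random_behavior_script(n_events = 6, seed = 99)
  sim <- simulate_area_series(script, s0 = 150, noise_sd = 0)
  ev <- detect_events(diff_series(sim$series), threshold = 0.2)
  tr <- sim$truth$events
  expect_equal(nrow(ev), nrow(tr))
  expect_equal(ev$start_frame, tr$start_frame)
  expect_equal(ev$end_frame, tr$end_frame)
  expect_equal(ev$area_mm2, tr$area_mm2)
  expect_equal(ev$rate_mm2_per_min, tr$rate_mm2_per_min)
  # sub-threshold events are correctly missed
  slow <- behavior_script(data.frame(start_min = 5, duration_min = 10,
                                     rate_mm2_per_min = 0.15))
  sim2 <- simulate_area_series(slow, s0 = 50, noise_sd = 0)
  expect_equal(nrow(detect_events(diff_series(sim2$series))), 0)
})

test_that("intervals on a synthetic schedule reconstruct the scripted gaps", {
  script <- random_behavior_script(n_events = 5, gap_range = c(5, 40), seed = 3)
  sim <- simulate_area_series(script, s0 = 150)
  ev <- compute_intervals(detect_events(diff_series(sim$series)))
  sched <- script$events
  gaps <- sched$start_min[-1] - (sched$start_min + sched$duration_min)[-5]
  # stated convention: start(next) - end(current), one frame more than the gap
  expect_equal(ev$interval_to_next_min[-5], gaps + 1)
  expect_equal(ev$interval_to_next_min[-5],
               sim$truth$events$interval_to_next_min[-5])
})
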