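#' Scripted feeding-behavior schedule
#'
#' A behavior script fixes the ground truth of a synthetic assay: when the
#' larva feeds, how fast, for how long, and where on the leaf. Events must
#' not overlap in time. Sites are 0-based (row, col) pixel coordinates used
#' by \code{\link{render_sequence}}; they may be omitted for pure area-series
#' simulation.
#'
#' @param events Data frame with columns \code{start_min},
#'   \code{duration_min}, \code{rate_mm2_per_min} and optionally
#'   \code{site_row}, \code{site_col}.
#' @param larva_path Optional data frame with per-frame \code{row},
#'   \code{col} (0-based) and logical \code{visible}; rows are recycled to
#'   the stack length (last position held).
#' @param seed RNG seed used by the generators for noise.
#' @return A \code{behavior_script}.
#' @export
behavior_script <- function(events, larva_path = NULL, seed = 1) {
  stopifnot(is.data.frame(events),
            all(c("start_min", "duration_min", "rate_mm2_per_min") %in%
                  names(events)))
  events <- events[order(events$start_min), , drop = FALSE]
  stopifnot(all(events$duration_min > 0), all(events$rate_mm2_per_min > 0),
            all(events$start_min >= 0))
  if (nrow(events) >= 2) {
    ends <- events$start_min + events$duration_min
    if (any(events$start_min[-1] < ends[-nrow(events)])) {
      stop("scripted events overlap in time", call. = FALSE)
    }
  }
  structure(list(events = events, larva_path = larva_path, seed = seed),
            class = "behavior_script")
}

#' Random feeding schedule generator
#'
#' Draws a plausible intermittent-feeding schedule: event count, rates,
#' durations and inter-event gaps sampled uniformly from the given ranges.
#' Durations and gaps are whole minutes so that events align with 1-min
#' frames. When a \code{scene} is given, feeding sites are sampled inside
#' the central part of the leaf.
#'
#' @param n_events Number of events, or a length-2 range to sample from.
#' @param rate_range Feeding rate range, mm^2 min^-1.
#' @param duration_range Event duration range, whole minutes.
#' @param gap_range Inter-event gap range, whole minutes.
#' @param first_start Start of the first event (min).
#' @param scene Optional \code{\link{scene_spec}} for site sampling.
#' @param seed RNG seed (also stored in the script).
#' @return A \code{\link{behavior_script}}.
#' @export
random_behavior_script <- function(n_events = c(8, 15),
                                   rate_range = c(0.3, 1.5),
                                   duration_range = c(2, 10),
                                   gap_range = c(5, 60),
                                   first_start = 5, scene = NULL, seed = 1) {
  with_seed(seed, {
    n <- if (length(n_events) == 2) {
      sample(n_events[1]:n_events[2], 1)
    } else as.integer(n_events)
    dur <- sample(duration_range[1]:duration_range[2], n, replace = TRUE)
    gap <- sample(gap_range[1]:gap_range[2], n - 1, replace = TRUE)
    rate <- stats::runif(n, rate_range[1], rate_range[2])
    start <- first_start + cumsum(c(0, dur[-n] + gap))
    ev <- data.frame(start_min = start, duration_min = dur,
                     rate_mm2_per_min = rate)
    if (!is.null(scene)) {
      sites <- sample_leaf_sites(scene, n)
      ev$site_row <- sites[, 1]
      ev$site_col <- sites[, 2]
    }
    behavior_script(ev, seed = seed)
  })
}

# Evaluate expr under a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

sample_leaf_sites <- function(scene, n) {
  th <- stats::runif(n, 0, 2 * pi)
  rad <- sqrt(stats::runif(n, 0, 0.4))   # keep sites in the leaf's inner 60%
  cbind(round(scene$leaf_center[1] + rad * scene$leaf_radii[1] * sin(th)),
        round(scene$leaf_center[2] + rad * scene$leaf_radii[2] * cos(th)))
}

#' Simulate a leaf-area time series with known truth
#'
#' The noiseless series is the initial area minus the cumulative scripted
#' consumption (each event removes area linearly at its rate over its
#' duration); i.i.d. Gaussian measurement noise is added on top. The
#' returned truth carries the exact per-event parameters and the event
#' start/end frames in derivative indices (the loss of event starting at
#' minute \eqn{s} with duration \eqn{d} occupies derivative points
#' \eqn{s/\Delta + 1} to \eqn{(s+d)/\Delta} for frame interval
#' \eqn{\Delta}), plus the inter-event intervals under the
#' start-minus-end frame convention used by \code{\link{compute_intervals}}.
#'
#' @param script A \code{\link{behavior_script}}.
#' @param s0 Initial leaf area, mm^2.
#' @param noise_sd Measurement noise SD, mm^2 (default 0).
#' @param frame_interval Minutes per frame.
#' @param n_frames Stack length; default runs 10 min past the last event.
#' @return List with \code{series} (a \code{\link{leaf_area_series}}-shaped
#'   data frame) and \code{truth} (event table with \code{start_frame},
#'   \code{end_frame}, \code{area_mm2}, \code{duration_min},
#'   \code{rate_mm2_per_min}, \code{interval_to_next_min}; plus \code{s0}
#'   and \code{total_consumed_mm2}).
#' @export
simulate_area_series <- function(script, s0 = 120, noise_sd = 0,
                                 frame_interval = 1, n_frames = NULL) {
  stopifnot(inherits(script, "behavior_script"))
  ev <- script$events
  total <- sum(ev$rate_mm2_per_min * ev$duration_min)
  if (total > s0) {
    stop("scripted consumption (", round(total, 2),
         " mm2) exceeds initial leaf area (", s0, " mm2)", call. = FALSE)
  }
  last_end <- if (nrow(ev)) max(ev$start_min + ev$duration_min) else 0
  n_frames <- n_frames %||% (ceiling((last_end + 10) / frame_interval) + 1)
  minutes <- (seq_len(n_frames) - 1) * frame_interval
  cum <- cumulative_consumption(ev, minutes)
  s <- s0 - cum
  if (noise_sd > 0) {
    s <- with_seed(script$seed, s + stats::rnorm(n_frames, 0, noise_sd))
  }
  series <- data.frame(frame = seq_len(n_frames), minutes = minutes,
                       area_px = NA_real_, area_mm2 = s)
  attr(series, "roi_label") <- "synthetic"
  attr(series, "calibration") <- NA_real_
  attr(series, "frame_interval") <- frame_interval
  class(series) <- c("leaf_area_series", "data.frame")
  list(series = series,
       truth = c(truth_events(ev, frame_interval),
                 list(s0 = s0, total_consumed_mm2 = total)))
}

cumulative_consumption <- function(events, minutes) {
  cum <- numeric(length(minutes))
  for (i in seq_len(nrow(events))) {
    s <- events$start_min[i]; d <- events$duration_min[i]
    r <- events$rate_mm2_per_min[i]
    cum <- cum + r * pmin(pmax(minutes - s, 0), d)
  }
  cum
}

truth_events <- function(events, frame_interval) {
  n <- nrow(events)
  if (n == 0) return(list(events = events))
  start_frame <- as.integer(floor(events$start_min / frame_interval)) + 1L
  end_frame <- as.integer(ceiling((events$start_min + events$duration_min) /
                                    frame_interval))
  iv <- if (n >= 2) {
    c((start_frame[-1] - end_frame[-n]) * frame_interval, NA_real_)
  } else NA_real_
  list(events = data.frame(
    event_id = seq_len(n),
    start_frame = start_frame, end_frame = end_frame,
    duration_min = events$duration_min,
    area_mm2 = events$rate_mm2_per_min * events$duration_min,
    rate_mm2_per_min = events$rate_mm2_per_min,
    interval_to_next_min = iv))
}

#' Synthetic scene description
#'
#' Geometry, calibration and colors of a rendered synthetic assay. The two
#' modes mirror the two scanning set-ups: \code{"reflective"} is a green
#' elliptical leaf on a dark background, \code{"transmissive"} a dark leaf
#' silhouette on a back-lit white background. Larva palettes:
#' \code{"leaf_like"} (a green that collides with the leaf color — the
#' white-butterfly-larva case) and \code{"dark_patterned"} (near-black — the
#' dark noctuid-larva case, invisible to the reflective threshold).
#'
#' @param width,height Image size in pixels.
#' @param mm_per_px Calibration (default 0.2 mm/px, i.e. 127 dpi).
#' @param scan_mode \code{"reflective"} or \code{"transmissive"}.
#' @param leaf_center,leaf_radii Ellipse center (row, col) and radii
#'   (rows, cols) in pixels; defaults fill most of the frame.
#' @param larva_palette \code{"leaf_like"} or \code{"dark_patterned"}.
#' @param larva_radii Larva ellipse radii (rows, cols) in pixels.
#' @param noise_sd Per-channel Gaussian color noise SD (8-bit scale / 255).
#' @return A \code{scene_spec}.
#' @export
scene_spec <- function(width = 160, height = 120, mm_per_px = 0.2,
                       scan_mode = c("reflective", "transmissive"),
                       leaf_center = NULL, leaf_radii = NULL,
                       larva_palette = c("leaf_like", "dark_patterned"),
                       larva_radii = c(4, 7), noise_sd = 0.01) {
  scan_mode <- match.arg(scan_mode)
  larva_palette <- match.arg(larva_palette)
  leaf_center <- leaf_center %||% c(height / 2, width / 2)
  leaf_radii <- leaf_radii %||% c(height * 0.35, width * 0.35)
  cols <- if (scan_mode == "reflective") {
    list(background = c(0.05, 0.05, 0.06),
         leaf = as.vector(grDevices::col2rgb(grDevices::hsv(0.33, 0.7, 0.55))) / 255)
  } else {
    list(background = c(0.97, 0.97, 0.97),
         leaf = c(0.15, 0.30, 0.12))
  }
  cols$larva <- switch(larva_palette,
    leaf_like = as.vector(grDevices::col2rgb(grDevices::hsv(0.30, 0.60, 0.50))) / 255,
    dark_patterned = c(0.07, 0.06, 0.05))
  structure(list(width = as.integer(width), height = as.integer(height),
                 mm_per_px = mm_per_px, scan_mode = scan_mode,
                 leaf_center = leaf_center, leaf_radii = leaf_radii,
                 colors = cols, larva_palette = larva_palette,
                 larva_radii = larva_radii, noise_sd = noise_sd),
            class = "scene_spec")
}

ellipse_mask <- function(height, width, center, radii) {
  r <- matrix(seq_len(height), height, width)
  c <- matrix(seq_len(width), height, width, byrow = TRUE)
  ((r - 1 - center[1]) / radii[1])^2 + ((c - 1 - center[2]) / radii[2])^2 <= 1
}

#' Render a synthetic time-lapse stack with ground truth
#'
#' Builds the image sequence a scanner would have produced under the script:
#' the leaf loses pixels radially around each event's site at the scripted
#' rate (pixel-quantized, so per-event mark areas are exact to one pixel), a
#' larva blob moves along \code{script$larva_path}, and Gaussian color noise
#' is added. The returned ground truth is the oracle for every downstream
#' stage: per-frame remaining-leaf masks and areas, per-event frames/areas,
#' and per-event mark masks with centroids (0-based pixel coordinates).
#'
#' With the same script (including its seed) and scene the output is
#' bit-identical between calls.
#'
#' @param script A \code{\link{behavior_script}} with site columns.
#' @param scene A \code{\link{scene_spec}}.
#' @param frame_interval Minutes per frame.
#' @param n_frames Stack length; default runs 10 min past the last event.
#' @param dir If non-NULL, frames are written there as serial-numbered PNGs
#'   (\code{frame_0001.png}, ...) together with a machine-readable
#'   \code{manifest.json} holding the script, scene summary and truth
#'   tables.
#' @return List with \code{frames} (an in-memory \code{frame_series}),
#'   \code{truth} (list: \code{remaining_masks}, \code{area_px},
#'   \code{area_mm2}, \code{leaf_mask}, \code{events},
#'   \code{marks} = per-event list with \code{mask}, \code{area_px},
#'   \code{centroid}), and \code{files}/\code{dir} when written.
#' @export
render_sequence <- function(script, scene, frame_interval = 1,
                            n_frames = NULL, dir = NULL) {
  stopifnot(inherits(script, "behavior_script"), inherits(scene, "scene_spec"))
  ev <- script$events
  if (nrow(ev) && !all(c("site_row", "site_col") %in% names(ev))) {
    stop("script events need site_row/site_col for rendering", call. = FALSE)
  }
  cal <- scene$mm_per_px
  h <- scene$height; w <- scene$width
  leaf <- ellipse_mask(h, w, scene$leaf_center, scene$leaf_radii)
  last_end <- if (nrow(ev)) max(ev$start_min + ev$duration_min) else 0
  n_frames <- n_frames %||% (ceiling((last_end + 10) / frame_interval) + 1)
  minutes <- (seq_len(n_frames) - 1) * frame_interval

  # Per-event consumed-pixel ordering: nearest remaining leaf pixels first.
  avail <- leaf
  cand <- vector("list", nrow(ev))
  n_final <- integer(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    site <- c(ev$site_row[i], ev$site_col[i])         # 0-based
    if (!leaf[site[1] + 1, site[2] + 1]) {
      stop("event ", i, " site (", site[1], ",", site[2],
           ") lies outside the leaf", call. = FALSE)
    }
    n_final[i] <- as.integer(round(ev$rate_mm2_per_min[i] *
                                     ev$duration_min[i] / cal^2))
    idx <- which(avail)
    rr <- (idx - 1L) %% h
    cc <- (idx - 1L) %/% h
    d2 <- (rr - site[1])^2 + (cc - site[2])^2
    ord <- idx[order(d2, idx)]
    if (n_final[i] > length(ord)) {
      stop("scripted consumption exceeds remaining leaf area at event ", i,
           call. = FALSE)
    }
    cand[[i]] <- ord[seq_len(n_final[i])]
    avail[cand[[i]]] <- FALSE
  }

  # Per-frame consumed counts per event (pixel-quantized linear growth).
  n_at <- function(i, m) {
    frac <- pmin(pmax(m - ev$start_min[i], 0), ev$duration_min[i]) /
      ev$duration_min[i]
    round(n_final[i] * frac)
  }
  remaining <- vector("list", n_frames)
  area_px <- integer(n_frames)
  counts <- vapply(seq_len(nrow(ev)), function(i) n_at(i, minutes),
                   numeric(n_frames))
  if (nrow(ev) == 0) counts <- matrix(0, n_frames, 0)
  for (t in seq_len(n_frames)) {
    m <- leaf
    for (i in seq_len(nrow(ev))) {
      k <- counts[t, i]
      if (k > 0) m[cand[[i]][seq_len(k)]] <- FALSE
    }
    remaining[[t]] <- m
    area_px[t] <- sum(m)
  }

  # Larva path, recycled to stack length.
  path <- script$larva_path
  if (!is.null(path)) {
    if (!"visible" %in% names(path)) path$visible <- TRUE
    take <- pmin(seq_len(n_frames), nrow(path))
    path <- path[take, , drop = FALSE]
  }

  frames <- with_seed(script$seed, lapply(seq_len(n_frames), function(t) {
    img <- array(rep(scene$colors$background, each = h * w), c(h, w, 3))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[remaining[[t]]] <- scene$colors$leaf[ch]
      img[, , ch] <- plane
    }
    if (!is.null(path) && isTRUE(path$visible[t])) {
      larva <- ellipse_mask(h, w, c(path$row[t], path$col[t]),
                            scene$larva_radii)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[larva] <- scene$colors$larva[ch]
        img[, , ch] <- plane
      }
    }
    if (scene$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, scene$noise_sd)
    }
    # 8-bit quantization, as a scanner would deliver
    round(pmin(pmax(img, 0), 1) * 255) / 255
  }))

  truth_ev <- truth_events(ev, frame_interval)$events
  if (!is.null(truth_ev) && nrow(truth_ev)) {
    truth_ev$area_px <- n_final
    truth_ev$area_mm2_px <- n_final * cal^2
  }
  marks <- lapply(seq_len(nrow(ev)), function(i) {
    m <- matrix(FALSE, h, w)
    m[cand[[i]]] <- TRUE
    idx <- which(m, arr.ind = TRUE)
    list(event_id = i, mask = m, area_px = n_final[i],
         centroid = c(row = mean(idx[, 1] - 1), col = mean(idx[, 2] - 1)))
  })
  fs <- structure(
    list(frames = frames, serial = seq_len(n_frames), files = NULL,
         frame_interval = frame_interval, calibration = cal,
         scan_mode = scene$scan_mode),
    class = "frame_series")
  out <- list(frames = fs,
              truth = list(remaining_masks = remaining, area_px = area_px,
                           area_mm2 = area_px * cal^2, leaf_mask = leaf,
                           events = truth_ev, marks = marks))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- vapply(seq_len(n_frames), function(t) {
      p <- file.path(dir, sprintf("frame_%04d.png", t))
      write_image(frames[[t]], p)
      p
    }, "")
    manifest <- list(
      scene = scene[c("width", "height", "mm_per_px", "scan_mode",
                      "larva_palette", "noise_sd")],
      script = list(events = ev, seed = script$seed),
      truth = list(events = truth_ev,
                   area_px = area_px,
                   area_mm2 = area_px * cal^2,
                   mark_centroids = do.call(rbind, lapply(marks, function(m) {
                     data.frame(event_id = m$event_id, row = m$centroid["row"],
                                col = m$centroid["col"], area_px = m$area_px)
                   }))))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    fs$files <- files
    out$frames <- fs
    out$files <- files
    out$dir <- dir
  }
  out
}
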