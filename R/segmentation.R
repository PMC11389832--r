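#' Color threshold specification
#'
#' Defines the foreground rule for \code{\link{color_threshold}}: a pixel is
#' foreground iff every constrained channel falls inside its inclusive
#' range. Channels are expressed in \code{[0, 1]}: for \code{"RGB"} the
#' channels are \code{r}, \code{g}, \code{b}; for \code{"HSV"} they are
#' \code{h}, \code{s}, \code{v} as returned by \code{grDevices::rgb2hsv}
#' (hue 0 = red, 1/3 = green, 2/3 = blue). Hue is circular: a range with
#' \code{min > max} wraps through 0 (e.g. \code{c(0.9, 0.1)} selects reds).
#'
#' Two presets mirror the two scanning set-ups:
#' \describe{
#'   \item{\code{"reflective"}}{sensor-side illumination with a dark
#'     background: foreground is a green hue window with minimum saturation
#'     and value (\code{h} in [0.16, 0.50], \code{s} >= 0.25,
#'     \code{v} >= 0.15).}
#'   \item{\code{"transmissive"}}{back-lit white background: foreground is
#'     anything dark (\code{v} <= 0.5), so both leaf and larva silhouettes
#'     are captured.}
#' }
#' The preset ranges are package defaults chosen on the synthetic scenes and
#' should be overridden per dataset when scanning conditions differ.
#'
#' @param color_space \code{"RGB"} or \code{"HSV"}.
#' @param ... Named channel ranges, each a length-2 numeric \code{c(min, max)}
#'   in [0, 1]. At least one channel must be constrained.
#' @return A \code{threshold_spec}.
#' @export
threshold_spec <- function(color_space = c("HSV", "RGB"), ...) {
  color_space <- match.arg(color_space)
  ranges <- list(...)
  valid <- if (color_space == "HSV") c("h", "s", "v") else c("r", "g", "b")
  if (length(ranges) == 0) {
    stop("at least one channel range must be given", call. = FALSE)
  }
  if (!all(names(ranges) %in% valid)) {
    stop("unknown channel(s) for ", color_space, ": ",
         paste(setdiff(names(ranges), valid), collapse = ", "), call. = FALSE)
  }
  for (ch in names(ranges)) {
    rg <- ranges[[ch]]
    stopifnot(length(rg) == 2, all(is.finite(rg)))
    circular <- color_space == "HSV" && ch == "h"
    if (!circular && rg[1] > rg[2]) {
      stop("channel '", ch, "': min > max", call. = FALSE)
    }
  }
  structure(list(color_space = color_space, ranges = ranges),
            class = "threshold_spec")
}

#' @rdname threshold_spec
#' @param preset \code{"reflective"} or \code{"transmissive"}.
#' @export
threshold_preset <- function(preset = c("reflective", "transmissive")) {
  preset <- match.arg(preset)
  spec <- switch(preset,
    reflective   = threshold_spec("HSV", h = c(0.16, 0.50),
                                  s = c(0.25, 1), v = c(0.15, 1)),
    transmissive = threshold_spec("HSV", v = c(0, 0.5))
  )
  spec$preset <- preset
  spec
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat("threshold_spec (", x$color_space,
      if (!is.null(x$preset)) paste0(", preset '", x$preset, "'"), "):\n",
      sep = "")
  for (ch in names(x$ranges)) {
    cat(sprintf("  %s in [%g, %g]\n", ch, x$ranges[[ch]][1], x$ranges[[ch]][2]))
  }
  invisible(x)
}

#' Segment frames by color thresholding (mask1)
#'
#' Applies a \code{\link{threshold_spec}} to every frame: a pixel is
#' foreground iff all constrained channels fall in range. No morphological
#' cleanup is applied; the downstream robustness mechanism is
#' \code{\link{cumulative_mask}}. An optional minimum connected-component
#' size filter is available but off by default.
#'
#' @param frames A \code{\link{read_frame_sequence}} result.
#' @param spec A \code{threshold_spec}, or a preset name for
#'   \code{\link{threshold_preset}}. Defaults to the preset matching
#'   \code{frames$scan_mode}.
#' @param min_component_px If > 0, drop 4-connected foreground components
#'   smaller than this many pixels (optional despeckling, default 0 = off).
#' @return A \code{mask_series} with \code{stage = "mask1"}.
#' @export
color_threshold <- function(frames, spec = NULL, min_component_px = 0) {
  stopifnot(inherits(frames, "frame_series"))
  if (is.null(spec)) spec <- threshold_preset(frames$scan_mode)
  if (is.character(spec)) spec <- threshold_preset(spec)
  stopifnot(inherits(spec, "threshold_spec"))
  gray <- length(dim(frames$frames[[1]])) == 2
  if (gray && spec$color_space == "HSV") {
    stop("HSV threshold spec cannot be applied to grayscale frames",
         call. = FALSE)
  }
  masks <- lapply(frames$frames, function(img) {
    m <- threshold_one(img, spec)
    if (min_component_px > 0) m <- drop_small_components(m, min_component_px)
    m
  })
  mask_series(masks, stage = "mask1", calibration = frames$calibration,
              frame_interval = frames$frame_interval)
}

threshold_one <- function(img, spec) {
  d <- dim(img)
  gray <- length(d) == 2
  if (spec$color_space == "HSV") {
    rgb <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                 as.vector(img[, , 3]))
    hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
    ch <- list(h = hsv[1, ], s = hsv[2, ], v = hsv[3, ])
  } else {
    ch <- if (gray) {
      v <- as.vector(img)
      list(r = v, g = v, b = v)
    } else {
      list(r = as.vector(img[, , 1]), g = as.vector(img[, , 2]),
           b = as.vector(img[, , 3]))
    }
  }
  keep <- rep(TRUE, length(ch[[1]]))
  for (name in names(spec$ranges)) {
    rg <- spec$ranges[[name]]
    x <- ch[[name]]
    keep <- keep & if (spec$color_space == "HSV" && name == "h" && rg[1] > rg[2]) {
      x >= rg[1] | x <= rg[2]          # circular hue window through 0
    } else {
      x >= rg[1] & x <= rg[2]
    }
  }
  matrix(keep, nrow = d[1], ncol = d[2])
}

# 4-connected component-size filter via two-pass flood fill on a label queue.
drop_small_components <- function(mask, min_px) {
  lab <- label_components(mask)
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  mask & matrix(lab %in% keep & lab > 0, nrow(mask), ncol(mask))
}

label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- (p - 1L) %% nr + 1L
      cc <- (p - 1L) %/% nr + 1L
      for (q in c(if (r > 1) p - 1L, if (r < nr) p + 1L,
                  if (cc > 1) p - nr, if (cc < nc) p + nr)) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- nxt
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

#' Construct a mask series
#'
#' @param masks List of logical matrices of identical dimensions.
#' @param stage \code{"mask1"} (raw threshold) or \code{"mask2"}
#'   (cumulative-filtered).
#' @param calibration mm per pixel edge.
#' @param frame_interval Minutes per frame.
#' @return A \code{mask_series}.
#' @export
mask_series <- function(masks, stage = c("mask1", "mask2"),
                        calibration = 1, frame_interval = 1) {
  stage <- match.arg(stage)
  stopifnot(length(masks) >= 1, is.logical(masks[[1]]))
  d <- dim(masks[[1]])
  ok <- vapply(masks, function(m) identical(dim(m), d), TRUE)
  if (!all(ok)) stop("mask dimension mismatch at frame ", which(!ok)[1],
                     call. = FALSE)
  structure(list(masks = masks, stage = stage, calibration = calibration,
                 frame_interval = frame_interval),
            class = "mask_series")
}

#' @export
print.mask_series <- function(x, ...) {
  d <- dim(x$masks[[1]])
  cat(sprintf("mask_series (%s): %d frames, %dx%d px\n", x$stage,
              length(x$masks), d[1], d[2]))
  invisible(x)
}

#' @export
length.mask_series <- function(x) length(x$masks)

#' Cumulative time-difference masking (mask2)
#'
#' Starting from the first frame, every pixel that is background at frame
#' \eqn{t} is forced to background at frame \eqn{t+1}:
#' \deqn{mask2(1) = mask1(1), \quad mask2(t+1) = mask1(t+1) \wedge mask2(t).}
#' Under the assumption that a consumed leaf pixel never returns, this
#' removes false-positive leaf pixels caused by insect bodies whose color
#' collides with the leaf: the insect moves, the pixels it occupied go
#' background once, and they stay background even if the insect (or anything
#' leaf-colored) covers them again later.
#'
#' A consequence worth knowing: a pixel that flickers to background for a
#' single frame (sensor noise) is also deleted permanently. That is the
#' stated behavior of the algorithm, mitigated by threshold choice, not by
#' any silent repair here.
#'
#' @param mask1 A \code{mask_series} (any stage; typically mask1).
#' @return A \code{mask_series} with \code{stage = "mask2"} whose foreground
#'   sets are nested (non-increasing) over time.
#' @export
cumulative_mask <- function(mask1) {
  stopifnot(inherits(mask1, "mask_series"))
  out <- vector("list", length(mask1$masks))
  out[[1]] <- mask1$masks[[1]]
  if (length(out) > 1) {
    for (t in seq_len(length(out) - 1)) {
      out[[t + 1]] <- mask1$masks[[t + 1]] & out[[t]]
    }
  }
  mask_series(out, stage = "mask2", calibration = mask1$calibration,
              frame_interval = mask1$frame_interval)
}

#' Measure per-ROI leaf area over time
#'
#' Counts foreground pixels of each mask frame inside each ROI and converts
#' to mm^2 with \code{area_mm2 = area_px * calibration^2}. Masking is done on
#' full frames first (see \code{\link{cumulative_mask}}); ROIs only restrict
#' the measurement.
#'
#' @param masks A \code{mask_series} (normally stage mask2).
#' @param rois List of \code{\link{rect_roi}} (or a single one).
#' @param calibration mm per pixel edge; defaults to the series' own.
#' @return Named list (by ROI label) of \code{leaf_area_series} data frames
#'   with columns \code{frame}, \code{minutes}, \code{area_px},
#'   \code{area_mm2}.
#' @export
measure_roi_areas <- function(masks, rois, calibration = NULL) {
  stopifnot(inherits(masks, "mask_series"))
  if (inherits(rois, "rect_roi")) rois <- list(rois)
  calibration <- calibration %||% masks$calibration
  d <- dim(masks$masks[[1]])
  out <- lapply(rois, function(roi) {
    check_roi_bounds(roi, d[1], d[2])
    px <- vapply(masks$masks, function(m) {
      sum(m[roi_rows(roi), roi_cols(roi)])
    }, 0L)
    leaf_area_series(px, roi_label = roi$label, calibration = calibration,
                     frame_interval = masks$frame_interval)
  })
  names(out) <- vapply(rois, `[[`, "", "label")
  out
}

#' Leaf area series for one ROI
#'
#' @param area_px Integer vector of per-frame foreground pixel counts.
#' @param roi_label ROI label.
#' @param calibration mm per pixel edge.
#' @param frame_interval Minutes per frame.
#' @return Data frame (class \code{leaf_area_series}) with columns
#'   \code{frame} (1-based), \code{minutes} (frame 1 = minute 0),
#'   \code{area_px}, \code{area_mm2}; ROI label, calibration and frame
#'   interval kept as attributes.
#' @export
leaf_area_series <- function(area_px, roi_label = "roi", calibration = 1,
                             frame_interval = 1) {
  n <- length(area_px)
  out <- data.frame(frame = seq_len(n),
                    minutes = (seq_len(n) - 1) * frame_interval,
                    area_px = as.numeric(area_px),
                    area_mm2 = as.numeric(area_px) * calibration^2)
  attr(out, "roi_label") <- roi_label
  attr(out, "calibration") <- calibration
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("leaf_area_series", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
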