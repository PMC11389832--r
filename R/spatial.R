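#' Feeding-mark mask for one event
#'
#' The mark is the set of pixels consumed during the event: the difference
#' between the filtered leaf mask of the frame just before the loss begins
#' and the mask of the last frame of the event,
#' \code{mask2[start_frame] & !mask2[end_frame + 1]}. Event frames are
#' derivative indices (the loss at index \eqn{t} happens between mask frames
#' \eqn{t} and \eqn{t+1}), so \code{mask2[start_frame]} \emph{is} the frame
#' one before the first frame showing the loss. By mask2 monotonicity the
#' difference is exactly the pixels lost during the event, and marks of
#' distinct events are pixel-disjoint.
#'
#' @param mask2 A cumulative-filtered \code{mask_series}.
#' @param event One-row subset of a \code{\link{detect_events}} frame (or a
#'   list with \code{start_frame}, \code{end_frame}).
#' @param roi Optional \code{\link{rect_roi}}; when given the mark is
#'   restricted to the ROI.
#' @return Logical matrix (full frame, or ROI-cropped when \code{roi} is
#'   given).
#' @export
event_mark_mask <- function(mask2, event, roi = NULL) {
  stopifnot(inherits(mask2, "mask_series"))
  if (mask2$stage != "mask2") {
    warning("mark extraction expects a cumulative-filtered (mask2) series",
            call. = FALSE)
  }
  s <- event$start_frame; e <- event$end_frame
  n <- length(mask2$masks)
  if (s < 1 || e + 1 > n || s > e) {
    stop("event frames [", s, ", ", e, "] outside mask series (n = ", n, ")",
         call. = FALSE)
  }
  before <- mask2$masks[[s]]
  after <- mask2$masks[[e + 1]]
  mark <- before & !after
  if (!is.null(roi)) {
    check_roi_bounds(roi, nrow(mark), ncol(mark))
    mark <- mark[roi_rows(roi), roi_cols(roi), drop = FALSE]
  }
  mark
}

#' Center of gravity of a feeding mark
#'
#' Unweighted mean of the foreground pixel coordinates, 0-based (a pixel's
#' coordinate is its row/column index starting at 0). Millimetre coordinates
#' are pixel coordinates times the calibration, with x along columns and y
#' along rows.
#'
#' @param mark Logical matrix.
#' @param calibration mm per pixel edge.
#' @return List with \code{row}, \code{col} (0-based pixel coordinates) and
#'   \code{x_mm}, \code{y_mm}.
#' @export
mark_centroid <- function(mark, calibration = 1) {
  idx <- which(mark, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    stop("degenerate (empty) feeding mark: no pixels consumed", call. = FALSE)
  }
  r <- mean(idx[, 1] - 1)
  c <- mean(idx[, 2] - 1)
  list(row = r, col = c, x_mm = c * calibration, y_mm = r * calibration)
}

#' Extract all feeding marks for a set of events
#'
#' Computes the per-event mark masks, centroids and consecutive Euclidean
#' distances for one ROI. Millimetre coordinates have their origin at the
#' ROI's top-left corner (x = columns, y = rows). Events whose mark is empty
#' (possible when the event's area loss happened entirely outside the ROI)
#' are flagged and excluded from the spatial table with a warning.
#'
#' @param mask2 A cumulative-filtered \code{mask_series} (full frames).
#' @param events A \code{\link{detect_events}} result.
#' @param roi A \code{\link{rect_roi}}; when \code{NULL} the whole frame is
#'   one ROI.
#' @param calibration mm per pixel edge; defaults to the mask series' own.
#' @return A \code{feeding_marks} list; each element has \code{event_id},
#'   \code{mask} (ROI-cropped), \code{area_px}, \code{area_mm2},
#'   \code{centroid} (absolute 0-based pixel coordinates and ROI-origin mm
#'   coordinates), \code{start_frame}, \code{end_frame} and
#'   \code{dist_from_prev_mm} (\code{NA} for the first mark).
#' @export
extract_marks <- function(mask2, events, roi = NULL, calibration = NULL) {
  stopifnot(inherits(mask2, "mask_series"), inherits(events, "feeding_events"))
  calibration <- calibration %||% mask2$calibration
  d <- dim(mask2$masks[[1]])
  if (is.null(roi)) {
    roi <- rect_roi(attr(events, "roi_label") %||% "frame", 0, 0, d[1], d[2])
  }
  marks <- list()
  for (i in seq_len(nrow(events))) {
    m <- event_mark_mask(mask2, events[i, ], roi = roi)
    if (!any(m)) {
      warning("event ", events$event_id[i], " left no mark inside ROI '",
              roi$label, "'; excluded from spatial table", call. = FALSE)
      next
    }
    cen <- mark_centroid(m, calibration)
    marks[[length(marks) + 1]] <- list(
      event_id = events$event_id[i],
      mask = m,
      area_px = sum(m),
      area_mm2 = sum(m) * calibration^2,
      centroid = list(row = cen$row + roi$row0, col = cen$col + roi$col0,
                      x_mm = cen$x_mm, y_mm = cen$y_mm),
      start_frame = events$start_frame[i],
      end_frame = events$end_frame[i],
      dist_from_prev_mm = NA_real_
    )
  }
  marks <- structure(marks, class = "feeding_marks",
                     roi_label = roi$label, roi = roi,
                     calibration = calibration)
  consecutive_distances(marks)
}

#' Euclidean distances between consecutive feeding marks
#'
#' Fills \code{dist_from_prev_mm} for each mark after the first:
#' \eqn{\sqrt{\Delta x^2 + \Delta y^2}} between the centroids (in mm) of two
#' consecutive marks, ordered by event id.
#'
#' @param marks A \code{feeding_marks} list (ordered by event).
#' @return The same list with distances set.
#' @export
consecutive_distances <- function(marks) {
  stopifnot(inherits(marks, "feeding_marks"))
  if (length(marks) >= 2) {
    for (k in 2:length(marks)) {
      dx <- marks[[k]]$centroid$x_mm - marks[[k - 1]]$centroid$x_mm
      dy <- marks[[k]]$centroid$y_mm - marks[[k - 1]]$centroid$y_mm
      marks[[k]]$dist_from_prev_mm <- sqrt(dx^2 + dy^2)
    }
  }
  marks
}

#' Tabulate feeding marks
#'
#' @param marks A \code{\link{extract_marks}} result.
#' @return Data frame with one row per mark: \code{roi_label},
#'   \code{event_id}, \code{centroid_row}, \code{centroid_col} (absolute
#'   0-based pixels), \code{centroid_x_mm}, \code{centroid_y_mm} (origin at
#'   the ROI's top-left corner), \code{start_frame}, \code{end_frame},
#'   \code{dist_from_prev_mm}.
#' @export
marks_table <- function(marks) {
  stopifnot(inherits(marks, "feeding_marks"))
  if (length(marks) == 0) {
    return(data.frame(roi_label = character(0), event_id = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      centroid_x_mm = numeric(0), centroid_y_mm = numeric(0),
                      start_frame = integer(0), end_frame = integer(0),
                      dist_from_prev_mm = numeric(0)))
  }
  do.call(rbind, lapply(marks, function(m) {
    data.frame(roi_label = attr(marks, "roi_label"),
               event_id = m$event_id,
               centroid_row = m$centroid$row, centroid_col = m$centroid$col,
               centroid_x_mm = m$centroid$x_mm, centroid_y_mm = m$centroid$y_mm,
               start_frame = m$start_frame, end_frame = m$end_frame,
               dist_from_prev_mm = m$dist_from_prev_mm)
  }))
}

#' @export
print.feeding_marks <- function(x, ...) {
  cat(sprintf("feeding_marks: %d mark(s) in ROI '%s'\n", length(x),
              attr(x, "roi_label")))
  if (length(x)) print(marks_table(x), row.names = FALSE, digits = 4)
  invisible(x)
}
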