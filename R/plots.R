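#' Spatio-temporal overlay image for one feeding event
#'
#' Renders the classic feeding-mark overlay: against the first mask frame as
#' the reference, remaining leaf pixels are black, the mark of the event of
#' interest is magenta, marks of all earlier events are cyan, and the
#' background is white.
#'
#' @param mask2 The cumulative-filtered \code{mask_series} the marks came
#'   from.
#' @param marks A \code{\link{extract_marks}} result.
#' @param event_id Which event to highlight.
#' @return \code{H x W x 3} numeric array in [0, 1] (ROI-cropped to match
#'   the marks).
#' @export
render_event_overlay <- function(mask2, marks, event_id) {
  stopifnot(inherits(mask2, "mask_series"), inherits(marks, "feeding_marks"))
  ids <- vapply(marks, `[[`, 0L, "event_id")
  k <- match(event_id, ids)
  if (is.na(k)) stop("unknown event_id: ", event_id, call. = FALSE)
  roi <- attr(marks, "roi")
  ref <- mask2$masks[[1]][roi_rows(roi), roi_cols(roi), drop = FALSE]
  d <- dim(ref)
  img <- array(1, c(d[1], d[2], 3))                      # white background
  paint <- function(img, where, rgb) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[where] <- rgb[ch]
      img[, , ch] <- plane
    }
    img
  }
  img <- paint(img, ref, c(0, 0, 0))                     # reference leaf: black
  if (k > 1) {
    earlier <- Reduce(`|`, lapply(marks[seq_len(k - 1)], `[[`, "mask"))
    img <- paint(img, earlier, c(0, 1, 1))               # previous marks: cyan
  }
  img <- paint(img, marks[[k]]$mask, c(1, 0, 1))         # current mark: magenta
  img
}

#' Write per-event overlay images
#'
#' One PNG per mark, named \code{<roi>_event<k>.png}.
#'
#' @param mask2,marks As in \code{\link{render_event_overlay}}.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_event_overlays <- function(mask2, marks, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  roi_label <- attr(marks, "roi_label")
  paths <- vapply(marks, function(m) {
    p <- file.path(directory, sprintf("%s_event%d.png", roi_label, m$event_id))
    write_image(render_event_overlay(mask2, marks, m$event_id), p)
    p
  }, "")
  invisible(paths)
}

mark_order_palette <- function(n) {
  grDevices::hcl.colors(max(n, 2), "viridis")[seq_len(n)]
}

#' Feeding-position summary plot
#'
#' Plots the centroid of each feeding mark in mm (ROI origin, y increasing
#' downward as in the image), numbered and colored by the order in which the
#' marks were formed, with consecutive marks connected.
#'
#' @param marks A \code{\link{extract_marks}} result.
#' @export
render_position_plot <- function(marks) {
  tab <- marks_table(marks)
  if (nrow(tab) == 0) stop("no marks to plot", call. = FALSE)
  cols <- mark_order_palette(nrow(tab))
  plot(tab$centroid_x_mm, tab$centroid_y_mm, type = "n",
       xlab = "x (mm)", ylab = "y (mm)", ylim = rev(range(tab$centroid_y_mm)),
       main = sprintf("Feeding positions (%s)", attr(marks, "roi_label")))
  graphics::lines(tab$centroid_x_mm, tab$centroid_y_mm, col = "grey70")
  graphics::points(tab$centroid_x_mm, tab$centroid_y_mm, pch = 19, cex = 2.2,
                   col = cols)
  graphics::text(tab$centroid_x_mm, tab$centroid_y_mm,
                 labels = seq_len(nrow(tab)), col = "white", cex = 0.7)
  invisible(tab)
}

#' Distance-from-previous-mark plot
#'
#' Distance between consecutive feeding marks against feeding-event order,
#' colored to match \code{\link{render_position_plot}}.
#'
#' @param marks A \code{\link{extract_marks}} result.
#' @export
render_distance_plot <- function(marks) {
  tab <- marks_table(marks)
  if (nrow(tab) < 2) stop("need >= 2 marks for distances", call. = FALSE)
  ord <- seq_len(nrow(tab))
  cols <- mark_order_palette(nrow(tab))
  plot(ord[-1], tab$dist_from_prev_mm[-1], type = "b", pch = 19, cex = 1.5,
       col = cols[-1], xlab = "feeding mark order",
       ylab = "distance from previous mark (mm)",
       main = sprintf("Inter-mark distances (%s)", attr(marks, "roi_label")))
  invisible(tab)
}

#' Leaf-area loss rate diagnostic plot
#'
#' Plots \eqn{y = -\Delta S(t)} against time with detected feeding-event
#' runs highlighted in red and the detection threshold as a dashed line.
#'
#' @param d A \code{\link{diff_series}} result.
#' @param events The matching \code{\link{detect_events}} result.
#' @export
plot_loss_rate <- function(d, events) {
  thr <- attr(events, "threshold") %||% 0.2
  plot(d$minutes, d$loss_mm2_per_min, type = "l", col = "grey40",
       xlab = "time (min)", ylab = expression(-Delta * S[leaf] ~ (mm^2 ~ min^-1)),
       main = sprintf("Leaf-area loss rate (%s)",
                      attr(d, "roi_label") %||% ""))
  graphics::abline(h = thr, lty = 2, col = "grey60")
  for (i in seq_len(nrow(events))) {
    sel <- d$frame >= events$start_frame[i] & d$frame <= events$end_frame[i]
    graphics::lines(d$minutes[sel], d$loss_mm2_per_min[sel], col = "red", lwd = 2)
  }
  invisible(NULL)
}
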