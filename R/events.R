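#' Leaf-area loss rate (negative time derivative)
#'
#' For a leaf-area series \eqn{S(t)} the per-frame difference is
#' \eqn{\Delta S(t) = S(t+1) - S(t)}; feeding shows up as peaks in
#' \eqn{y = -\Delta S(t)}. The returned rate is divided by the frame interval
#' so its units are mm^2 per minute regardless of scan cadence.
#'
#' The loss at derivative index \eqn{t} is the area lost \emph{between}
#' frames \eqn{t} and \eqn{t+1}; event frame numbers downstream refer to
#' these derivative indices.
#'
#' @param series A \code{\link{leaf_area_series}} data frame, or a numeric
#'   vector of areas (mm^2).
#' @param frame_interval Minutes per frame (taken from the series attribute
#'   when available).
#' @return Data frame with columns \code{frame} (derivative index, 1 to
#'   n-1), \code{minutes} (time of the interval start) and
#'   \code{loss_mm2_per_min}.
#' @export
diff_series <- function(series, frame_interval = NULL) {
  if (inherits(series, "leaf_area_series")) {
    frame_interval <- frame_interval %||% attr(series, "frame_interval")
    s <- series$area_mm2
  } else {
    s <- as.numeric(series)
  }
  frame_interval <- frame_interval %||% 1
  if (length(s) < 2) {
    stop("leaf area series must have at least 2 frames", call. = FALSE)
  }
  d <- -diff(s) / frame_interval
  out <- data.frame(frame = seq_len(length(s) - 1),
                    minutes = (seq_len(length(s) - 1) - 1) * frame_interval,
                    loss_mm2_per_min = d)
  attr(out, "frame_interval") <- frame_interval
  attr(out, "roi_label") <- attr(series, "roi_label")
  out
}

#' Detect feeding events as above-threshold runs of leaf-area loss
#'
#' A feeding event is a maximal run of consecutive derivative points whose
#' loss rate strictly exceeds \code{threshold} (default 0.2 mm^2 min^-1),
#' with run length >= \code{min_run}. Per event:
#' \itemize{
#'   \item \code{area_mm2} — integrated area of the peak, the sum of
#'     loss-rate x frame-interval over the run;
#'   \item \code{duration_min} — run length x frame interval (peak width);
#'   \item \code{rate_mm2_per_min} — \code{area_mm2 / duration_min}.
#' }
#'
#' @param d A \code{\link{diff_series}} result, or a numeric loss-rate
#'   vector (mm^2 min^-1).
#' @param threshold Detection threshold in mm^2 min^-1 (strictly-greater
#'   comparison; default 0.2).
#' @param min_run Minimum run length in frames (default 1).
#' @param frame_interval Minutes per frame (from the series when available).
#' @return Data frame (class \code{feeding_events}) with one row per event:
#'   \code{event_id}, \code{start_frame}, \code{end_frame} (derivative
#'   indices, inclusive), \code{duration_min}, \code{area_mm2},
#'   \code{rate_mm2_per_min}, plus interval columns initialised to \code{NA}
#'   (see \code{\link{compute_intervals}}). Zero detected events gives a
#'   zero-row frame, not an error.
#' @export
detect_events <- function(d, threshold = 0.2, min_run = 1,
                          frame_interval = NULL) {
  stopifnot(threshold > 0, min_run >= 1)
  roi_label <- attr(d, "roi_label")
  if (is.data.frame(d)) {
    frame_interval <- frame_interval %||% attr(d, "frame_interval")
    d <- d$loss_mm2_per_min
  }
  frame_interval <- frame_interval %||% 1
  above <- d > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  starts <- starts[keep]; ends <- ends[keep]
  area <- vapply(seq_along(starts), function(i) {
    sum(d[starts[i]:ends[i]]) * frame_interval
  }, 0)
  duration <- (ends - starts + 1L) * frame_interval
  out <- data.frame(
    event_id = seq_along(starts),
    start_frame = as.integer(starts),
    end_frame = as.integer(ends),
    duration_min = as.numeric(duration),
    area_mm2 = area,
    rate_mm2_per_min = if (length(starts)) area / duration else numeric(0),
    interval_to_next_min = rep(NA_real_, length(starts)),
    interval_excluded = rep(NA, length(starts))
  )
  attr(out, "frame_interval") <- frame_interval
  attr(out, "threshold") <- threshold
  attr(out, "roi_label") <- roi_label
  class(out) <- c("feeding_events", "data.frame")
  out
}

#' Inter-event intervals with the molting cutoff
#'
#' The interval after event \eqn{k} is the distance from its end to the next
#' event's beginning, \code{(start_frame[k+1] - end_frame[k]) *
#' frame_interval} minutes. Intervals longer than \code{max_interval}
#' (default 100 min) are flagged \code{interval_excluded = TRUE}: they
#' mostly reflect molting and are omitted from interval summaries, while the
#' events themselves are retained for the other parameters.
#'
#' @param events A \code{\link{detect_events}} result (ordered,
#'   non-overlapping).
#' @param max_interval Exclusion cutoff in minutes (default 100).
#' @return The events frame with \code{interval_to_next_min} and
#'   \code{interval_excluded} filled in (both \code{NA} for the last event).
#' @export
compute_intervals <- function(events, max_interval = 100) {
  stopifnot(inherits(events, "feeding_events"), max_interval > 0)
  n <- nrow(events)
  if (n >= 2) {
    fi <- attr(events, "frame_interval") %||% 1
    iv <- (events$start_frame[-1] - events$end_frame[-n]) * fi
    events$interval_to_next_min <- c(iv, NA_real_)
    events$interval_excluded <- c(iv > max_interval, NA)
  }
  attr(events, "max_interval") <- max_interval
  events
}

#' @export
print.feeding_events <- function(x, ...) {
  cat(sprintf("feeding_events: %d event(s)", nrow(x)))
  if (!is.null(attr(x, "roi_label"))) cat(" in ROI '", attr(x, "roi_label"), "'", sep = "")
  cat("\n")
  if (nrow(x)) print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-assay summary: medians of the behavioral parameters
#'
#' One assay (one ROI / one larva) is summarised by the median of each
#' parameter over all feeding events whose start lies within the analysis
#' window (default 999 min from the first frame). The interval median uses
#' only non-excluded intervals of qualifying events. Medians over an even
#' number of events use the midpoint convention (\code{stats::median}).
#'
#' @param events A \code{\link{compute_intervals}} result.
#' @param window Analysis window in minutes (default 999). An event
#'   qualifies when its start time (start_frame - 1 frames after the first
#'   scan) is <= \code{window}.
#' @param group Optional genotype/group label carried into comparisons.
#' @return An \code{assay_summary} list: \code{roi_label}, \code{group},
#'   \code{n_events}, and medians \code{duration_min}, \code{area_mm2},
#'   \code{rate_mm2_per_min}, \code{interval_min} (each \code{NA} when no
#'   event qualifies; the assay is flagged via \code{n_events = 0}, not
#'   dropped).
#' @export
summarize_assay <- function(events, window = 999, group = NA_character_) {
  stopifnot(inherits(events, "feeding_events"), window > 0)
  fi <- attr(events, "frame_interval") %||% 1
  start_min <- (events$start_frame - 1) * fi
  q <- events[start_min <= window, , drop = FALSE]
  iv <- q$interval_to_next_min[!is.na(q$interval_to_next_min) &
                                 !q$interval_excluded]
  med <- function(x) if (length(x)) stats::median(x) else NA_real_
  structure(
    list(roi_label = attr(events, "roi_label") %||% NA_character_,
         group = group,
         n_events = nrow(q),
         duration_min = med(q$duration_min),
         area_mm2 = med(q$area_mm2),
         rate_mm2_per_min = med(q$rate_mm2_per_min),
         interval_min = med(iv),
         window = window),
    class = "assay_summary"
  )
}

#' @export
print.assay_summary <- function(x, ...) {
  cat(sprintf("assay_summary '%s'%s: %d event(s) in %g min window\n",
              x$roi_label,
              if (!is.na(x$group)) paste0(" [", x$group, "]") else "",
              x$n_events, x$window))
  cat(sprintf("  median duration %.3g min, area %.3g mm2, rate %.3g mm2/min, interval %.3g min\n",
              x$duration_min, x$area_mm2, x$rate_mm2_per_min, x$interval_min))
  invisible(x)
}

#' Welch's t-test between two groups of per-assay medians
#'
#' Compares one behavioral parameter between two groups of assays (e.g.
#' wild-type vs trichome-less leaves) using the unequal-variance t-test with
#' Welch-Satterthwaite degrees of freedom, on the per-assay median values.
#' Group means +/- sample SD (n - 1 denominator) are reported as plotted in
#' assay summaries.
#'
#' @param summaries_a,summaries_b Lists of \code{\link{summarize_assay}}
#'   results, or plain numeric vectors of per-assay medians.
#' @param parameter Which parameter to compare when summaries are given:
#'   \code{"duration_min"}, \code{"area_mm2"}, \code{"rate_mm2_per_min"} or
#'   \code{"interval_min"}.
#' @return A \code{group_comparison} list: \code{parameter}, per-group
#'   \code{n}, \code{mean}, \code{sd}, the Welch \code{t},
#'   \code{df} and two-sided \code{p}.
#' @export
compare_groups <- function(summaries_a, summaries_b,
                           parameter = c("rate_mm2_per_min", "duration_min",
                                         "area_mm2", "interval_min")) {
  parameter <- match.arg(parameter)
  pull <- function(x) {
    if (is.numeric(x)) return(as.numeric(x))
    v <- vapply(x, function(s) {
      stopifnot(inherits(s, "assay_summary"))
      s[[parameter]]
    }, 0)
    v[!is.na(v)]
  }
  a <- pull(summaries_a); b <- pull(summaries_b)
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs >= 2 assays with a defined median (got ",
         length(a), " and ", length(b), ")", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  structure(
    list(parameter = parameter,
         n_a = length(a), mean_a = mean(a), sd_a = stats::sd(a),
         n_b = length(b), mean_b = mean(b), sd_b = stats::sd(b),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Welch's t-test on '%s' (per-assay medians)\n", x$parameter))
  cat(sprintf("  group A: n=%d, mean %.4g +/- %.4g\n", x$n_a, x$mean_a, x$sd_a))
  cat(sprintf("  group B: n=%d, mean %.4g +/- %.4g\n", x$n_b, x$mean_b, x$sd_b))
  cat(sprintf("  t = %.4g, df = %.4g, P = %.4g\n", x$t, x$df, x$p))
  invisible(x)
}
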