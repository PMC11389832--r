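#' Write per-ROI leaf-area series to CSV
#'
#' Long format, columns \code{frame,minutes,roi_label,area_mm2,area_px}.
#' An optional config hash is recorded as a leading \code{# config_md5:}
#' comment line (skipped by \code{\link{read_area_csv}}).
#'
#' @param series_list Named list of \code{\link{leaf_area_series}} (or one).
#' @param path Output file.
#' @param config_md5 Optional run-configuration hash.
#' @export
write_area_csv <- function(series_list, path, config_md5 = NULL) {
  if (inherits(series_list, "leaf_area_series")) series_list <- list(series_list)
  tab <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(frame = s$frame, minutes = s$minutes,
               roi_label = attr(s, "roi_label"),
               area_mm2 = s$area_mm2, area_px = s$area_px)
  }))
  write_csv_commented(tab, path, config_md5)
}

#' Read a leaf-area CSV back into per-ROI series
#'
#' @param path A \code{\link{write_area_csv}} file.
#' @param calibration,frame_interval Calibration metadata to re-attach
#'   (CSV stores values, not metadata).
#' @return Named list of \code{\link{leaf_area_series}}.
#' @export
read_area_csv <- function(path, calibration = 1, frame_interval = NULL) {
  tab <- utils::read.csv(path, comment.char = "#")
  need <- c("frame", "minutes", "roi_label", "area_mm2", "area_px")
  if (!all(need %in% names(tab))) {
    stop("area CSV must have columns: ", paste(need, collapse = ","),
         call. = FALSE)
  }
  out <- lapply(split(tab, tab$roi_label), function(g) {
    g <- g[order(g$frame), , drop = FALSE]
    fi <- frame_interval %||%
      (if (nrow(g) > 1) g$minutes[2] - g$minutes[1] else 1)
    s <- data.frame(frame = g$frame, minutes = g$minutes,
                    area_px = g$area_px, area_mm2 = g$area_mm2)
    attr(s, "roi_label") <- g$roi_label[1]
    attr(s, "calibration") <- calibration
    attr(s, "frame_interval") <- fi
    class(s) <- c("leaf_area_series", "data.frame")
    s
  })
  out[order(names(out))]
}

#' Write detected feeding events to CSV
#'
#' Columns: \code{roi_label,event_id,start_frame,end_frame,duration_min,}
#' \code{area_mm2,rate_mm2_per_min,interval_to_next_min,interval_excluded}.
#' Zero events yields a header-only file.
#'
#' @param events A \code{\link{detect_events}} result, or a named list of
#'   them (one per ROI).
#' @param path Output file.
#' @param config_md5 Optional run-configuration hash.
#' @export
write_events_csv <- function(events, path, config_md5 = NULL) {
  if (inherits(events, "feeding_events")) events <- list(events)
  tab <- do.call(rbind, lapply(events, function(e) {
    data.frame(roi_label = rep(attr(e, "roi_label") %||% NA_character_,
                               nrow(e)),
               event_id = e$event_id,
               start_frame = e$start_frame, end_frame = e$end_frame,
               duration_min = e$duration_min, area_mm2 = e$area_mm2,
               rate_mm2_per_min = e$rate_mm2_per_min,
               interval_to_next_min = e$interval_to_next_min,
               interval_excluded = e$interval_excluded)[seq_len(nrow(e)), ,
                                                        drop = FALSE]
  }))
  if (is.null(tab)) {
    tab <- data.frame(roi_label = character(0), event_id = integer(0),
                      start_frame = integer(0), end_frame = integer(0),
                      duration_min = numeric(0), area_mm2 = numeric(0),
                      rate_mm2_per_min = numeric(0),
                      interval_to_next_min = numeric(0),
                      interval_excluded = logical(0))
  }
  write_csv_commented(tab, path, config_md5)
}

#' Write feeding-mark tables to CSV
#'
#' Columns as in \code{\link{marks_table}}, prefixed by the ROI label. The
#' mm coordinates are relative to each ROI's top-left corner.
#'
#' @param marks A \code{\link{extract_marks}} result, or a list of them.
#' @param path Output file.
#' @param config_md5 Optional run-configuration hash.
#' @export
write_marks_csv <- function(marks, path, config_md5 = NULL) {
  if (inherits(marks, "feeding_marks")) marks <- list(marks)
  tab <- do.call(rbind, lapply(marks, marks_table))
  write_csv_commented(tab, path, config_md5)
}

write_csv_commented <- function(tab, path, config_md5 = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_md5)) {
    writeLines(paste0("# config_md5: ", config_md5), con)
  }
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a mask series as single-channel PNGs
#'
#' One file per frame (\code{<stage>_0001.png}, ...), foreground 255,
#' background 0. The roundtrip through \code{\link{read_mask_series}} is
#' pixel-exact.
#'
#' @param masks A \code{mask_series}.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_mask_series <- function(masks, directory) {
  stopifnot(inherits(masks, "mask_series"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(masks$masks), function(t) {
    p <- file.path(directory, sprintf("%s_%04d.png", masks$stage, t))
    png::writePNG(masks$masks[[t]] * 1, p)
    p
  }, "")
  invisible(paths)
}

#' Read a mask series written by \code{\link{write_mask_series}}
#'
#' @param directory Directory of mask PNGs.
#' @param stage Mask stage recorded on the result.
#' @param calibration,frame_interval Metadata to attach.
#' @return A \code{mask_series}.
#' @export
read_mask_series <- function(directory, stage = c("mask2", "mask1"),
                             calibration = 1, frame_interval = 1) {
  stage <- match.arg(stage)
  files <- Sys.glob(file.path(directory, paste0(stage, "_*.png")))
  if (length(files) == 0) {
    stop("no ", stage, " PNGs found in ", directory, call. = FALSE)
  }
  files <- files[order(filename_serial(files))]
  masks <- lapply(files, function(f) png::readPNG(f) > 0.5)
  mask_series(masks, stage = stage, calibration = calibration,
              frame_interval = frame_interval)
}
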