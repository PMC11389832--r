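#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end pipeline with the standard
#' defaults: detection threshold 0.2 mm^2 min^-1, minimum run 1 frame,
#' interval cutoff 100 min, analysis window 999 min, 1-min frames.
#'
#' @param input_dir Directory of time-lapse frames.
#' @param roi_path ROI file (ImageJ zip or CSV table); \code{NULL} means one
#'   ROI covering the whole frame.
#' @param pattern Filename glob for the frames.
#' @param frame_interval Minutes per frame.
#' @param dpi,mm_per_px Calibration (exactly one).
#' @param scan_mode \code{"reflective"} or \code{"transmissive"}.
#' @param threshold_spec A \code{\link{threshold_spec}} or preset name;
#'   default is the preset matching \code{scan_mode}.
#' @param detect_threshold Event-detection threshold, mm^2 min^-1.
#' @param min_run Minimum event run length, frames.
#' @param max_interval Interval exclusion cutoff, minutes.
#' @param window Per-assay summary window, minutes.
#' @param exclude_rois Character vector of ROI labels to drop (manual QC).
#' @param out_dir Output directory.
#' @return A \code{run_config} list.
#' @export
run_config <- function(input_dir, roi_path = NULL, pattern = "*.png",
                       frame_interval = 1, dpi = NULL, mm_per_px = NULL,
                       scan_mode = "reflective", threshold_spec = NULL,
                       detect_threshold = 0.2, min_run = 1,
                       max_interval = 100, window = 999,
                       exclude_rois = character(0), out_dir = "feedmark_out") {
  cfg <- list(input_dir = input_dir, roi_path = roi_path, pattern = pattern,
              frame_interval = frame_interval, dpi = dpi,
              mm_per_px = mm_per_px, scan_mode = scan_mode,
              threshold_spec = threshold_spec,
              detect_threshold = detect_threshold, min_run = min_run,
              max_interval = max_interval, window = window,
              exclude_rois = exclude_rois, out_dir = out_dir)
  stopifnot(cfg$frame_interval > 0, cfg$detect_threshold > 0,
            cfg$min_run >= 1, cfg$max_interval > 0, cfg$window > 0)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys are the \code{\link{run_config}} arguments; a
#' \code{threshold_spec} block may give \code{preset} or
#' \code{color_space} plus named channel ranges. \code{overrides}
#' (a named list, e.g. from CLI flags) win over file values.
#'
#' @param path YAML config file.
#' @param overrides Named list of values overriding the file.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw[names(overrides)] <- overrides
  ts <- raw$threshold_spec
  if (!is.null(ts) && is.list(ts)) {
    raw$threshold_spec <- if (!is.null(ts$preset)) {
      threshold_preset(ts$preset)
    } else {
      do.call(threshold_spec,
              c(list(color_space = ts$color_space %||% "HSV"),
                ts[setdiff(names(ts), "color_space")]))
    }
  }
  if (!is.null(raw$exclude_rois)) raw$exclude_rois <- unlist(raw$exclude_rois)
  known <- names(formals(run_config))
  do.call(run_config, raw[intersect(names(raw), known)])
}

# Hash of the analysis-relevant configuration (the output location does not
# change the analysis, so it is left out).
config_fingerprint <- function(cfg) {
  dump <- tempfile(fileext = ".yaml")
  on.exit(unlink(dump))
  keep <- serializable_config(cfg)
  keep$out_dir <- NULL
  yaml::write_yaml(keep, dump)
  unname(tools::md5sum(dump))
}

serializable_config <- function(cfg) {
  out <- unclass(cfg)
  if (inherits(out$threshold_spec, "threshold_spec")) {
    out$threshold_spec <- unclass(out$threshold_spec)
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: read frames, color threshold (mask1),
#' cumulative time-difference masking (mask2), per-ROI area measurement,
#' event detection and behavioral parameters, feeding-mark extraction, and
#' writes the result bundle under \code{config$out_dir}: \code{areas.csv},
#' \code{events.csv}, \code{marks.csv}, per-event overlay PNGs, diagnostic
#' plots, the effective config (\code{config.yaml}) and a run log. Every
#' CSV carries the config MD5 as a leading comment line. Excluded ROIs are
#' dropped from all outputs and noted in the log.
#'
#' @param config A \code{\link{run_config}} (or path to a YAML file).
#' @param write_overlays Write per-event overlay PNGs (default TRUE).
#' @return Invisibly, a list with \code{areas}, \code{events}, \code{marks},
#'   \code{summaries}, \code{config_md5} and output paths.
#' @export
run_pipeline <- function(config, write_overlays = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$out_dir, "run.log")
  logcon <- file(logfile, "w")
  on.exit(close(logcon))
  say <- function(stage, ...) {
    msg <- paste0("[", stage, "] ", ...)
    writeLines(msg, logcon)
    message(msg)
  }

  md5 <- config_fingerprint(config)
  yaml::write_yaml(serializable_config(config),
                   file.path(config$out_dir, "config.yaml"))
  say("config", "md5 ", md5)

  frames <- wrap_stage("read", read_frame_sequence(
    config$input_dir, pattern = config$pattern,
    frame_interval = config$frame_interval, dpi = config$dpi,
    mm_per_px = config$mm_per_px, scan_mode = config$scan_mode))
  say("read", length(frames), " frames from ", config$input_dir)

  mask1 <- wrap_stage("mask1", color_threshold(frames, config$threshold_spec))
  mask2 <- wrap_stage("mask2", cumulative_mask(mask1))
  say("mask2", "cumulative masking done")

  d <- dim(mask2$masks[[1]])
  rois <- if (is.null(config$roi_path)) {
    list(rect_roi("frame", 0, 0, d[1], d[2]))
  } else {
    wrap_stage("rois", read_rois(config$roi_path))
  }
  labels <- vapply(rois, `[[`, "", "label")
  drop <- labels %in% config$exclude_rois
  if (any(drop)) say("rois", "excluded by config: ",
                     paste(labels[drop], collapse = ", "))
  rois <- rois[!drop]
  if (length(rois) == 0) stop("[rois] all ROIs excluded", call. = FALSE)
  say("rois", length(rois), " ROI(s): ",
      paste(vapply(rois, `[[`, "", "label"), collapse = ", "))

  areas <- wrap_stage("areas", measure_roi_areas(mask2, rois))
  write_area_csv(areas, file.path(config$out_dir, "areas.csv"), md5)

  events <- list(); marks <- list(); summaries <- list()
  for (roi in rois) {
    lab <- roi$label
    s <- areas[[lab]]
    dd <- diff_series(s)
    ev <- detect_events(dd, threshold = config$detect_threshold,
                        min_run = config$min_run)
    ev <- compute_intervals(ev, max_interval = config$max_interval)
    say("events", lab, ": ", nrow(ev), " event(s)")
    events[[lab]] <- ev
    summaries[[lab]] <- summarize_assay(ev, window = config$window)
    mk <- wrap_stage("marks", extract_marks(mask2, ev, roi = roi))
    marks[[lab]] <- mk
    if (write_overlays && length(mk)) {
      write_event_overlays(mask2, mk,
                           file.path(config$out_dir, "overlays"))
    }
    grDevices::png(file.path(config$out_dir,
                             sprintf("loss_rate_%s.png", lab)),
                   width = 900, height = 420)
    plot_loss_rate(dd, ev)
    grDevices::dev.off()
    if (length(mk) >= 2) {
      grDevices::png(file.path(config$out_dir,
                               sprintf("positions_%s.png", lab)),
                     width = 480, height = 480)
      render_position_plot(mk)
      grDevices::dev.off()
      grDevices::png(file.path(config$out_dir,
                               sprintf("distances_%s.png", lab)),
                     width = 480, height = 360)
      render_distance_plot(mk)
      grDevices::dev.off()
    }
  }
  write_events_csv(events, file.path(config$out_dir, "events.csv"), md5)
  write_marks_csv(marks, file.path(config$out_dir, "marks.csv"), md5)
  say("done", "outputs in ", config$out_dir)
  invisible(list(areas = areas, events = events, marks = marks,
                 summaries = summaries, config_md5 = md5,
                 out_dir = config$out_dir))
}

wrap_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}
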