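#' Read a serial-numbered time-lapse image sequence
#'
#' Loads all images in \code{directory} matching \code{pattern}, orders them
#' by the decimal serial number that ends each filename (numeric order, so
#' \code{leaf_10.png} sorts after \code{leaf_2.png}), and returns a calibrated
#' \code{frame_series}. Gaps in the serial numbers are allowed: frames are
#' treated as consecutive scans spaced \code{frame_interval} minutes apart and
#' a warning reports the missing serials.
#'
#' @param directory Directory containing the frames.
#' @param pattern Filename glob (e.g. \code{"*.png"}). Default matches
#'   JPEG/PNG/TIFF files.
#' @param frame_interval Minutes between consecutive frames (default 1).
#' @param dpi Scan resolution in dots per inch. The pixel calibration is
#'   \code{25.4 / dpi} mm per pixel edge. Give either \code{dpi} or
#'   \code{mm_per_px}.
#' @param mm_per_px Pixel calibration in mm per pixel edge.
#' @param scan_mode \code{"reflective"} (dark background, colored objects) or
#'   \code{"transmissive"} (back-lit: white background, dark silhouettes).
#' @return A \code{frame_series}: list with \code{frames} (arrays in
#'   \code{[0, 1]}, \code{H x W x 3} for color or \code{H x W} for
#'   grayscale), \code{serial} (filename serial numbers), \code{files},
#'   \code{frame_interval}, \code{calibration} (mm/px) and \code{scan_mode}.
#' @export
read_frame_sequence <- function(directory, pattern = "*.{png,PNG,jpg,JPG,jpeg,tif,tiff}",
                                frame_interval = 1, dpi = NULL, mm_per_px = NULL,
                                scan_mode = c("reflective", "transmissive")) {
  scan_mode <- match.arg(scan_mode)
  calibration <- resolve_calibration(dpi, mm_per_px)
  stopifnot(frame_interval > 0)
  if (!dir.exists(directory)) {
    stop("input directory not found: ", directory, call. = FALSE)
  }
  files <- Sys.glob(file.path(directory, pattern))
  if (length(files) < 2) {
    stop("need at least 2 frames matching '", pattern, "' in ", directory,
         call. = FALSE)
  }
  serial <- filename_serial(files)
  ord <- order(serial)
  files <- files[ord]
  serial <- serial[ord]
  if (anyDuplicated(serial)) {
    stop("duplicate frame serial number in: ",
         basename(files[duplicated(serial)][1]), call. = FALSE)
  }
  gaps <- diff(serial)
  if (any(gaps > 1)) {
    warning(sum(gaps - 1), " missing serial number(s) in frame sequence; ",
            "frames are treated as consecutive scans", call. = FALSE)
  }
  frames <- lapply(files, read_image)
  d1 <- dim3(frames[[1]])
  for (i in seq_along(frames)) {
    if (!identical(dim3(frames[[i]]), d1)) {
      stop("frame dimension mismatch: ", basename(files[i]), " is ",
           paste(dim3(frames[[i]]), collapse = "x"), ", expected ",
           paste(d1, collapse = "x"), call. = FALSE)
    }
  }
  structure(
    list(frames = frames, serial = serial, files = files,
         frame_interval = frame_interval, calibration = calibration,
         scan_mode = scan_mode),
    class = "frame_series"
  )
}

#' @export
print.frame_series <- function(x, ...) {
  d <- dim3(x$frames[[1]])
  cat(sprintf("frame_series: %d frames, %dx%d px, %d channel(s)\n",
              length(x$frames), d[1], d[2], d[3]))
  cat(sprintf("  frame interval %g min, calibration %g mm/px, %s mode\n",
              x$frame_interval, x$calibration, x$scan_mode))
  invisible(x)
}

#' @export
length.frame_series <- function(x) length(x$frames)

resolve_calibration <- function(dpi = NULL, mm_per_px = NULL) {
  if (is.null(dpi) == is.null(mm_per_px)) {
    stop("give exactly one of dpi or mm_per_px", call. = FALSE)
  }
  cal <- if (is.null(mm_per_px)) 25.4 / dpi else mm_per_px
  if (!is.finite(cal) || cal <= 0) stop("calibration must be > 0", call. = FALSE)
  cal
}

# Trailing decimal serial before the extension; errors name the file.
filename_serial <- function(files) {
  base <- basename(files)
  m <- regmatches(base, regexpr("[0-9]+\\.[A-Za-z]+$", base))
  bad <- !grepl("[0-9]+\\.[A-Za-z]+$", base)
  if (any(bad)) {
    stop("no serial frame number before the extension in filename: ",
         base[which(bad)[1]], call. = FALSE)
  }
  as.integer(sub("\\..*$", "", m))
}

dim3 <- function(img) {
  d <- dim(img)
  if (length(d) == 2) c(d, 1L) else d
}

#' Read a single image file as a numeric array in [0, 1]
#'
#' Dispatches on the file extension (PNG, JPEG, TIFF). Alpha channels are
#' dropped; grayscale images come back as a matrix.
#'
#' @param path Image file.
#' @return Numeric array, \code{H x W x 3} or \code{H x W}, values in [0, 1].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", path, call. = FALSE)
  )
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3) img <- img[, , 1:3, drop = FALSE]
    else img <- img[, , 1]          # single-channel stored as HxWx1
  }
  img
}

#' Write a numeric image array to PNG
#'
#' @param img Numeric array in [0, 1] (\code{H x W} or \code{H x W x 3}).
#' @param path Output file.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}
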