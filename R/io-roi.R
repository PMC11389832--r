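#' Rectangular region of interest (one cage)
#'
#' Coordinates are 0-based and half-open: the ROI covers pixel rows
#' \code{[row0, row0 + height)} and columns \code{[col0, col0 + width)}.
#'
#' @param label ROI label (cage name).
#' @param row0,col0 Top-left corner, 0-based.
#' @param height,width Extent in pixels, both >= 1.
#' @return A \code{rect_roi} list.
#' @export
rect_roi <- function(label, row0, col0, height, width) {
  row0 <- as.integer(row0); col0 <- as.integer(col0)
  height <- as.integer(height); width <- as.integer(width)
  if (height < 1 || width < 1) {
    stop("ROI '", label, "': height and width must be >= 1", call. = FALSE)
  }
  if (row0 < 0 || col0 < 0) {
    stop("ROI '", label, "': row0/col0 must be >= 0", call. = FALSE)
  }
  structure(list(label = as.character(label), row0 = row0, col0 = col0,
                 height = height, width = width),
            class = "rect_roi")
}

#' @export
print.rect_roi <- function(x, ...) {
  cat(sprintf("rect_roi '%s': rows [%d,%d) x cols [%d,%d)\n", x$label,
              x$row0, x$row0 + x$height, x$col0, x$col0 + x$width))
  invisible(x)
}

#' Read rectangular ROIs from a file
#'
#' Two formats are supported, distinguished by content: a zip-compressed
#' ImageJ ROI archive (rectangle ROIs only; labels come from the archive
#' entry names) or a plain CSV table with header
#' \code{label,row0,col0,height,width} in 0-based half-open pixel
#' coordinates. ImageJ rectangle records (top/left/bottom/right) are
#' converted with \code{row0 = top}, \code{col0 = left},
#' \code{height = bottom - top}, \code{width = right - left}.
#'
#' Out-of-bounds ROIs are not rejected here; they are caught when the ROI is
#' applied to a frame of known size.
#'
#' @param path ROI zip archive or CSV table.
#' @return List of \code{\link{rect_roi}}.
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop("ROI file not found: ", path, call. = FALSE)
  magic <- readBin(path, "raw", n = 4)
  if (length(magic) >= 2 && magic[1] == as.raw(0x50) && magic[2] == as.raw(0x4b)) {
    read_rois_imagej_zip(path)
  } else {
    read_rois_table(path)
  }
}

read_rois_table <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  need <- c("label", "row0", "col0", "height", "width")
  if (!all(need %in% names(tab))) {
    stop("ROI table must have columns: ", paste(need, collapse = ","),
         call. = FALSE)
  }
  lapply(seq_len(nrow(tab)), function(i) {
    rect_roi(tab$label[i], tab$row0[i], tab$col0[i], tab$height[i], tab$width[i])
  })
}

read_rois_imagej_zip <- function(path) {
  exdir <- tempfile("rois")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  entries <- utils::unzip(path, exdir = exdir)
  entries <- entries[grepl("\\.roi$", entries, ignore.case = TRUE)]
  if (length(entries) == 0) stop("no .roi entries in archive: ", path, call. = FALSE)
  lapply(entries, function(f) {
    read_imagej_roi(f, label = sub("\\.roi$", "", basename(f), ignore.case = TRUE))
  })
}

# ImageJ .roi binary record: "Iout" magic, version short, type byte at offset
# 6, then top/left/bottom/right as big-endian signed shorts at offsets 8-15.
IJ_ROI_RECT <- 1L

read_imagej_roi <- function(path, label) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "Iout")) {
    stop("not an ImageJ ROI record: '", label, "'", call. = FALSE)
  }
  readBin(con, "integer", n = 1, size = 2, endian = "big")  # version
  type <- readBin(con, "integer", n = 1, size = 1)
  readBin(con, "integer", n = 1, size = 1)                  # pad
  if (type != IJ_ROI_RECT) {
    stop("unsupported (non-rectangle) ImageJ ROI: '", label, "'", call. = FALSE)
  }
  tlbr <- readBin(con, "integer", n = 4, size = 2, endian = "big")
  rect_roi(label, row0 = tlbr[1], col0 = tlbr[2],
           height = tlbr[3] - tlbr[1], width = tlbr[4] - tlbr[2])
}

#' Write ROIs to a file
#'
#' \code{format = "table"} writes the plain CSV dialect
#' (\code{label,row0,col0,height,width}); \code{format = "imagej"} writes a
#' zip archive of ImageJ rectangle ROI records (one \code{<label>.roi} entry
#' per ROI). Both roundtrip through \code{\link{read_rois}} without loss.
#'
#' @param rois List of \code{\link{rect_roi}}.
#' @param path Output file.
#' @param format \code{"table"} or \code{"imagej"}.
#' @export
write_rois <- function(rois, path, format = c("table", "imagej")) {
  format <- match.arg(format)
  if (format == "table") {
    tab <- do.call(rbind, lapply(rois, function(r) {
      data.frame(label = r$label, row0 = r$row0, col0 = r$col0,
                 height = r$height, width = r$width)
    }))
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  } else {
    entries <- lapply(rois, imagej_roi_bytes)
    names(entries) <- vapply(rois, function(r) paste0(r$label, ".roi"), "")
    write_zip_stored(entries, path)
  }
  invisible(path)
}

imagej_roi_bytes <- function(roi) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeChar("Iout", con, eos = NULL, useBytes = TRUE)
  writeBin(226L, con, size = 2, endian = "big")           # version
  writeBin(c(IJ_ROI_RECT, 0L), con, size = 1)             # type + pad
  writeBin(as.integer(c(roi$row0, roi$col0,
                        roi$row0 + roi$height, roi$col0 + roi$width)),
           con, size = 2, endian = "big")
  writeBin(raw(64 - 16), con)                             # rest of the header
  rawConnectionValue(con)
}

# --- minimal ZIP writer (method 0 = stored) -------------------------------
# Enough of the ZIP format to package ImageJ .roi records; utils::unzip and
# ImageJ itself read the result.

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      poly <- -306674912L  # 0xEDB88320 as signed 32-bit
      t <- integer(256)
      for (i in 0:255) {
        c <- i
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) != 0L) {
            bitwXor(bitwShiftR(c, 1L), poly)
          } else bitwShiftR(c, 1L)
        }
        t[i + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8L), tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

write_zip_stored <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  offsets <- integer(length(entries))
  pos <- 0L
  crcs <- integer(length(entries))
  for (i in seq_along(entries)) {
    data <- entries[[i]]
    name <- charToRaw(names(entries)[i])
    crcs[i] <- crc32(data)
    offsets[i] <- pos
    w32(0x04034b50); w16(20); w16(0); w16(0); w16(0); w16(0)
    w32(crcs[i]); w32(length(data)); w32(length(data))
    w16(length(name)); w16(0)
    writeBin(name, con); writeBin(data, con)
    pos <- pos + 30L + length(name) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(entries)) {
    data <- entries[[i]]
    name <- charToRaw(names(entries)[i])
    w32(0x02014b50); w16(20); w16(20); w16(0); w16(0); w16(0); w16(0)
    w32(crcs[i]); w32(length(data)); w32(length(data))
    w16(length(name)); w16(0); w16(0); w16(0); w16(0); w32(0)
    w32(offsets[i])
    writeBin(name, con)
    pos <- pos + 46L + length(name)
  }
  w32(0x06054b50); w16(0); w16(0)
  w16(length(entries)); w16(length(entries))
  w32(pos - cd_start); w32(cd_start)
  w16(0)
  invisible(path)
}

# ROI bounds check against a frame/mask of known size; errors name the label.
check_roi_bounds <- function(roi, nrow, ncol) {
  if (roi$row0 + roi$height > nrow || roi$col0 + roi$width > ncol) {
    stop("ROI '", roi$label, "' exceeds frame bounds (", nrow, "x", ncol, ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

roi_rows <- function(roi) (roi$row0 + 1L):(roi$row0 + roi$height)
roi_cols <- function(roi) (roi$col0 + 1L):(roi$col0 + roi$width)
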