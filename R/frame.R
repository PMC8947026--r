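#' Calibrated ultrasound frame
#'
#' A frame is a grayscale intensity matrix with values in `[0, 1]`, row 1 at
#' the top (superficial / skin side), together with an isotropic pixel
#' calibration. Frames smaller than 16 x 16 are rejected.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`.
#' @param cm_per_px Positive isotropic calibration (centimetres per pixel).
#' @param frame_index Nonnegative integer index within a sequence.
#' @param timestamp_s Nonnegative acquisition time in seconds, or `NA`.
#' @return An object of class `pt_frame`.
#' @export
pt_frame <- function(pixels, cm_per_px, frame_index = 0L, timestamp_s = NA_real_) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    pt_stop("pt_validation_error", "pixels must be a numeric matrix")
  if (nrow(pixels) < 16L || ncol(pixels) < 16L)
    pt_stop("pt_validation_error", "image too small (%d x %d); at least 16 x 16 required",
            nrow(pixels), ncol(pixels))
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    pt_stop("pt_validation_error", "pixel values must lie in [0, 1]")
  if (!is.numeric(cm_per_px) || length(cm_per_px) != 1L || cm_per_px <= 0)
    pt_stop("pt_validation_error", "cm_per_px must be a positive scalar")
  if (frame_index < 0) pt_stop("pt_validation_error", "frame_index must be nonnegative")
  structure(list(pixels = pixels,
                 height_px = nrow(pixels), width_px = ncol(pixels),
                 cm_per_px = as.numeric(cm_per_px),
                 frame_index = as.integer(frame_index),
                 timestamp_s = as.numeric(timestamp_s)),
            class = "pt_frame")
}

#' @export
print.pt_frame <- function(x, ...) {
  cat(sprintf("<pt_frame> %d x %d px, %.4g cm/px, frame %d%s\n",
              x$height_px, x$width_px, x$cm_per_px, x$frame_index,
              if (is.finite(x$timestamp_s)) sprintf(", t = %.3f s", x$timestamp_s) else ""))
  invisible(x)
}

# Decode a PNG/TIFF file to a [0,1] grayscale matrix with row 1 = top.
# png::readPNG and tiff::readTIFF both rescale 8/16-bit integer data to
# [0,1]; RGB(A) input is converted to luma (Rec. 601 weights).
read_image_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    pt_stop("pt_io_error", "unsupported image format '%s' (use PNG or TIFF): %s", ext, path))
  to_gray(img, path)
}

to_gray <- function(img, what = "image") {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3]
    if (nch >= 3L)
      return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
    return(img[, , 1])
  }
  pt_stop("pt_io_error", "cannot interpret %s as a 2-D grayscale image", what)
}

#' Load a single ultrasound frame
#'
#' Reads a PNG or TIFF image (8- or 16-bit, grayscale or RGB), rescales
#' intensities to `[0, 1]` and attaches the pixel calibration. The image must
#' already be cropped to the echo window, with the superficial side at the
#' top.
#'
#' @param path Path to a PNG or TIFF file.
#' @param cm_per_px Positive isotropic calibration (cm per pixel).
#' @param frame_index,timestamp_s Passed to [pt_frame()].
#' @return A [pt_frame()].
#' @export
load_frame <- function(path, cm_per_px, frame_index = 0L, timestamp_s = NA_real_) {
  if (!file.exists(path)) pt_stop("pt_io_error", "file not found: %s", path)
  px <- tryCatch(read_image_gray(path), error = function(e)
    pt_stop("pt_io_error", "unreadable image %s: %s", path, conditionMessage(e)))
  pt_frame(pmin(pmax(px, 0), 1), cm_per_px, frame_index, timestamp_s)
}

# Natural sort: numeric runs inside file names compare numerically,
# so f2.png orders before f10.png.
natural_sort <- function(x) {
  toks <- regmatches(x, gregexpr("[0-9]+|[^0-9]+", x))
  n <- max(lengths(toks))
  keys <- lapply(seq_len(n), function(i) {
    tk <- vapply(toks, function(t) if (length(t) >= i) t[i] else "", "")
    num <- suppressWarnings(as.numeric(tk))
    if (all(!is.na(num) | tk == "")) ifelse(tk == "", -Inf, num) else tk
  })
  x[do.call(order, keys)]
}

#' Load an image sequence
#'
#' Accepts a directory of numbered PNG/TIFF frames (ordered by natural sort of
#' their file names) or a multi-page TIFF (page order). All frames must share
#' the same dimensions. When `frame_rate_hz` is given, frame `i` (0-based)
#' gets timestamp `i / frame_rate_hz`.
#'
#' @param path Directory of frames, or a multi-page TIFF file.
#' @param cm_per_px Positive isotropic calibration (cm per pixel).
#' @param frame_rate_hz Optional acquisition rate in Hz.
#' @return A list of [pt_frame()] objects.
#' @export
load_sequence <- function(path, cm_per_px, frame_rate_hz = NULL) {
  mats <- NULL
  names_for_err <- NULL
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
    if (!length(files)) pt_stop("pt_io_error", "no PNG/TIFF frames found in %s", path)
    files <- natural_sort(files)
    mats <- lapply(file.path(path, files), read_image_gray)
    names_for_err <- files
  } else if (file.exists(path)) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) {
      pages <- tiff::readTIFF(path, all = TRUE)
      if (is.matrix(pages) || length(dim(pages)) == 3L) pages <- list(pages)
      mats <- lapply(pages, to_gray)
      names_for_err <- sprintf("page %d", seq_along(mats))
    } else {
      mats <- list(read_image_gray(path))
      names_for_err <- basename(path)
    }
  } else pt_stop("pt_io_error", "no such file or directory: %s", path)

  dims <- vapply(mats, dim, integer(2))
  bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
  if (length(bad))
    pt_stop("pt_validation_error", "frame '%s' has dimensions %d x %d, expected %d x %d",
            names_for_err[bad[1]], dims[1, bad[1]], dims[2, bad[1]], dims[1, 1], dims[2, 1])
  lapply(seq_along(mats), function(i) {
    ts <- if (is.null(frame_rate_hz)) NA_real_ else (i - 1) / frame_rate_hz
    pt_frame(pmin(pmax(mats[[i]], 0), 1), cm_per_px, frame_index = i - 1L,
             timestamp_s = if (length(mats) == 1L && is.na(ts)) 0 else ts)
  })
}

#' Depth-region mask
#'
#' Binary mask selecting the rows of a relative depth range: row `r`
#' (1-based) is selected iff `lo * H <= r - 1 < hi * H`, all columns.
#'
#' @param frame A [pt_frame()].
#' @param region Numeric `c(lo, hi)` with `0 <= lo < hi <= 1`.
#' @return Logical matrix with the frame's dimensions.
#' @export
depth_region_mask <- function(frame, region) {
  stopifnot(inherits(frame, "pt_frame"))
  if (length(region) != 2L || region[1] >= region[2] || region[1] < 0 || region[2] > 1)
    pt_stop("pt_validation_error", "region must be [lo, hi] with 0 <= lo < hi <= 1")
  h <- frame$height_px
  rows <- (seq_len(h) - 1) >= region[1] * h & (seq_len(h) - 1) < region[2] * h
  matrix(rows, h, frame$width_px)
}

# Row index range of a depth region (used to restrict detection).
region_rows <- function(h, region) {
  which((seq_len(h) - 1) >= region[1] * h & (seq_len(h) - 1) < region[2] * h)
}
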