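#' Timelapse stack objects
#'
#' A `timelapse_stack` holds a single two-photon timelapse recording: a 3D
#' intensity array with acquisition metadata.  Frames are stored as an array
#' of dimension `(y, x, t)` so that `frames(stack)[, , k]` is the k-th frame;
#' pixel indices are 1-based and time runs in seconds from recording start,
#' with frame k spanning `[(k - 1), k) / frame_rate`.  Physical distances are
#' pixels times `pixel_size` (micrometres per pixel).
#'
#' @param frames numeric array `(y, x, t)` of non-negative, finite
#'   intensities, at least two frames.
#' @param frame_rate frames per second, positive.
#' @param pixel_size micrometres per pixel, positive.  The field-of-view
#'   magnification varies between experiments, so the pixel size must always
#'   be supplied with the data; it is never guessed.
#' @param recording_id opaque identifier used when stitching repeated
#'   recordings of the same field of view.
#' @return an object of class `timelapse_stack`.
#' @export
timelapse_stack <- function(frames, frame_rate, pixel_size,
                            recording_id = "rec") {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be a 3D array (y, x, t)")
  if (dim(frames)[3] < 2L) stop("≥2 frames required")
  if (!all(is.finite(frames))) stop("frames: intensities must be finite")
  if (any(frames < 0)) stop("frames: intensities must be non-negative")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("frame_rate must be a positive scalar")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a positive scalar")
  structure(list(frames = frames,
                 frame_rate = as.numeric(frame_rate),
                 pixel_size = as.numeric(pixel_size),
                 recording_id = as.character(recording_id),
                 qc = NULL),
            class = "timelapse_stack")
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "timelapse_stack '%s': %d frames of %d x %d px, %.3g fps, %.3g um/px\n",
    x$recording_id, d[3], d[1], d[2], x$frame_rate, x$pixel_size))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[3]
frame_times <- function(stack) (seq_len(n_frames(stack)) - 1) / stack$frame_rate

#' Read a timelapse stack from a multi-page TIFF
#'
#' Intensities are read as stored (no rescaling).  Acquisition metadata is
#' not carried by plain TIFF, so frame rate and pixel size must be supplied.
#'
#' @param path path to a grayscale multi-page TIFF with at least two frames.
#' @inheritParams timelapse_stack
#' @return a [timelapse_stack()].
#' @export
read_stack <- function(path, frame_rate, pixel_size,
                       recording_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) stop("≥2 frames required")
  shp <- dim(pages[[1]])
  if (length(shp) != 2L) stop("stack TIFF must be grayscale (one channel)")
  for (p in pages) if (!identical(dim(p), shp))
    stop("frame-shape mismatch across TIFF pages")
  frames <- array(unlist(pages), dim = c(shp, length(pages)))
  timelapse_stack(frames, frame_rate = frame_rate, pixel_size = pixel_size,
                  recording_id = recording_id)
}

#' Write a timelapse stack to a multi-page 16-bit TIFF
#'
#' Intensities are rounded to integers in `[0, 65535]`; integer-valued data
#' round-trips bit-identically through [read_stack()].
#'
#' @param stack a [timelapse_stack()].
#' @param path output path.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "timelapse_stack"))
  f <- stack$frames
  if (max(f) > 65535) stop("intensities exceed 16-bit range")
  pages <- lapply(seq_len(dim(f)[3]), function(k) round(f[, , k]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

# mean image across frames, optionally restricted to given frame indices
mean_image <- function(stack, frames_idx = NULL) {
  f <- stack$frames
  if (!is.null(frames_idx)) f <- f[, , frames_idx, drop = FALSE]
  rowMeans(f, dims = 2)
}
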