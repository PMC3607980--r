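#' Frame stack: ordered grayscale frames with a frame rate
#'
#' A `frame_stack` is the in-memory representation of a high-speed video
#' recording: a 3-D numeric array of pixel intensities indexed
#' `(frame, row, column)` together with the acquisition frame rate in Hz.
#' All downstream analysis (ROI traces, spectra, CBF) starts from this
#' container.
#'
#' @param frames numeric 3-D array indexed `(frame, row, column)`; all values
#'   must be finite and non-negative.
#' @param frame_rate acquisition rate in frames per second (Hz), `> 0`.
#' @param source_path provenance string (file path or `"<synthetic>"`).
#' @return An object of class `frame_stack`: a list with elements `frames`,
#'   `frame_rate` and `source_path`.
#' @examples
#' fs <- frame_stack(array(runif(8 * 4 * 4, 0, 255), c(8, 4, 4)), 250)
#' dim(fs$frames)
#' @export
frame_stack <- function(frames, frame_rate, source_path = "<memory>") {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be a 3-D array indexed (frame, row, column)",
         call. = FALSE)
  }
  d <- dim(frames)
  if (d[1L] < 2L) {
    stop("a frame stack needs at least 2 frames, got ", d[1L], call. = FALSE)
  }
  if (d[2L] < 1L || d[3L] < 1L) {
    stop("frame height and width must be >= 1", call. = FALSE)
  }
  storage.mode(frames) <- "double"
  if (anyNA(frames) || !all(is.finite(frames))) {
    stop("all pixel intensities must be finite", call. = FALSE)
  }
  if (min(frames) < 0) {
    stop("pixel intensities must be non-negative", call. = FALSE)
  }
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L ||
      !is.finite(frame_rate) || frame_rate <= 0) {
    stop("`frame_rate` must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(frames = frames, frame_rate = as.numeric(frame_rate),
         source_path = as.character(source_path)),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames, %d x %d px, %.4g fps (%s)\n",
              d[1L], d[2L], d[3L], x$frame_rate, x$source_path))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

#' Number of frames in a stack
#' @param stack a [frame_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  dim(stack$frames)[1L]
}

#' Spatially crop a frame stack
#'
#' Restricts every frame to a rectangular pixel region. Cropping is purely
#' spatial: the frame count and frame rate are untouched, so the spectral
#' frequency resolution (frame rate / number of frames) is unchanged --
#' cropping only speeds up computation on large fields, it never degrades
#' the frequency axis.
#'
#' @param stack a [frame_stack()].
#' @param x,y 1-based column (`x`) and row (`y`) of the region's top-left
#'   pixel.
#' @param width,height region extent in pixels, `>= 1`.
#' @return A [frame_stack()] covering only the requested region.
#' @examples
#' fs <- frame_stack(array(1, c(4, 20, 30)), 250)
#' dim(crop_stack(fs, x = 5, y = 3, width = 10, height = 8)$frames)
#' @export
crop_stack <- function(stack, x, y, width, height) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  x <- as.integer(x); y <- as.integer(y)
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L) {
    stop("crop width and height must be >= 1", call. = FALSE)
  }
  if (x < 1L || y < 1L || y + height - 1L > d[2L] || x + width - 1L > d[3L]) {
    stop(sprintf(
      "crop region (x=%d, y=%d, %dx%d) exceeds frame bounds (%d x %d)",
      x, y, width, height, d[2L], d[3L]), call. = FALSE)
  }
  frame_stack(
    stack$frames[, y:(y + height - 1L), x:(x + width - 1L), drop = FALSE],
    stack$frame_rate, stack$source_path
  )
}

#' Collapse an RGB frame array to grayscale
#'
#' @param rgb numeric 4-D array indexed `(frame, row, column, channel)` with
#'   3 channels.
#' @param method `"mean"` (default) averages the three channels, matching
#'   plain pixel-intensity semantics; `"luma"` applies ITU-R BT.601 weights
#'   (0.299, 0.587, 0.114).
#' @return numeric 3-D array `(frame, row, column)`.
#' @export
rgb_to_gray <- function(rgb, method = c("mean", "luma")) {
  method <- match.arg(method)
  stopifnot(is.array(rgb), length(dim(rgb)) == 4L, dim(rgb)[4L] == 3L)
  w <- if (method == "mean") c(1, 1, 1) / 3 else c(0.299, 0.587, 0.114)
  out <- rgb[, , , 1L, drop = FALSE] * w[1L] +
    rgb[, , , 2L, drop = FALSE] * w[2L] +
    rgb[, , , 3L, drop = FALSE] * w[3L]
  dim(out) <- dim(rgb)[1:3]
  out
}
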