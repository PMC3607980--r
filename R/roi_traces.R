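#' Partition a frame into a rectangular grid of regions of interest
#'
#' Frames are tiled with equal-sized rectangular ROIs, up to a 40 x 40 grid
#' (1600 regions). ROI size is the integer division of the frame extent by
#' the grid dimensions; remainder pixels at the right and bottom edges are
#' excluded so that every ROI covers exactly the same number of pixels,
#' which keeps spectral magnitudes comparable across regions.
#'
#' @param frame_height,frame_width frame extent in pixels.
#' @param n_rows,n_cols grid dimensions, each between 1 and 40.
#' @return An object of class `roi_grid` with fields `n_rows`, `n_cols`,
#'   `roi_height_px`, `roi_width_px` and `origin` (top-left pixel, 1-based
#'   `c(row, col)`).
#' @examples
#' make_grid(400, 400, 40, 40)    # 1600 ROIs of 10 x 10 px
#' @export
make_grid <- function(frame_height, frame_width, n_rows = 40L, n_cols = 40L) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L || n_rows > 40L || n_cols > 40L) {
    stop("grid dimensions must be between 1 and 40 (at most 1600 ROIs)",
         call. = FALSE)
  }
  rh <- frame_height %/% n_rows
  rw <- frame_width %/% n_cols
  if (rh < 1L || rw < 1L) {
    stop(sprintf(
      "frame (%d x %d px) too small for a %d x %d grid: each ROI needs >= 1 px",
      frame_height, frame_width, n_rows, n_cols), call. = FALSE)
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         roi_height_px = as.integer(rh), roi_width_px = as.integer(rw),
         origin = c(row = 1L, col = 1L)),
    class = "roi_grid"
  )
}

#' @export
print.roi_grid <- function(x, ...) {
  cat(sprintf("<roi_grid> %d x %d ROIs of %d x %d px each (%d regions)\n",
              x$n_rows, x$n_cols, x$roi_height_px, x$roi_width_px,
              x$n_rows * x$n_cols))
  invisible(x)
}

#' Largest grid (up to 40 x 40) that fits a frame
#'
#' @param frame_height,frame_width frame extent in pixels.
#' @return A [make_grid()] result with `min(40, extent)` rows/columns.
#' @export
default_grid <- function(frame_height, frame_width) {
  make_grid(frame_height, frame_width,
            min(40L, frame_height), min(40L, frame_width))
}

# 1-based pixel ranges of ROI (r, c)
.roi_rows <- function(grid, r) {
  ((r - 1L) * grid$roi_height_px + 1L):(r * grid$roi_height_px)
}
.roi_cols <- function(grid, c) {
  ((c - 1L) * grid$roi_width_px + 1L):(c * grid$roi_width_px)
}

#' Extract per-ROI mean-intensity time series
#'
#' The rhythmic change in light intensity around beating cilia is captured
#' by averaging all pixel intensities inside each ROI on every frame; the
#' resulting ROI x frame matrix is the raw signal submitted to Fourier
#' analysis. ROIs are ordered row-major (ROI index = (row - 1) * n_cols +
#' col).
#'
#' @param stack a [frame_stack()].
#' @param grid a [make_grid()] result that fits inside the stack's frames.
#' @return An object of class `intensity_traces`: a list with `values`
#'   (numeric matrix, ROI x frame), `grid` and `frame_rate`.
#' @export
extract_traces <- function(stack, grid) {
  stopifnot(inherits(stack, "frame_stack"), inherits(grid, "roi_grid"))
  d <- dim(stack$frames)
  if (grid$n_rows * grid$roi_height_px > d[2L] ||
      grid$n_cols * grid$roi_width_px > d[3L]) {
    stop(sprintf("grid (%d x %d ROIs of %d x %d px) does not fit a %d x %d frame",
                 grid$n_rows, grid$n_cols, grid$roi_height_px,
                 grid$roi_width_px, d[2L], d[3L]), call. = FALSE)
  }
  nf <- d[1L]
  n_roi <- grid$n_rows * grid$n_cols
  # block-average: collapse columns into column-blocks, then rows into
  # row-blocks, on the (frame x row, col) flattened matrix
  covered_r <- grid$n_rows * grid$roi_height_px
  covered_c <- grid$n_cols * grid$roi_width_px
  sub <- stack$frames[, seq_len(covered_r), seq_len(covered_c), drop = FALSE]
  # dims: (frame, row, col) -> average over col within each col-block
  m <- matrix(sub, nrow = nf * covered_r, ncol = covered_c)
  col_block <- rep(seq_len(grid$n_cols), each = grid$roi_width_px)
  csum <- m %*% outer(col_block, seq_len(grid$n_cols), "==")
  # csum: (frame x row, col_block); now average rows within row-blocks
  a <- array(csum, c(nf, covered_r, grid$n_cols))
  row_block <- rep(seq_len(grid$n_rows), each = grid$roi_height_px)
  values <- matrix(0, nrow = n_roi, ncol = nf)
  npix <- grid$roi_height_px * grid$roi_width_px
  for (rb in seq_len(grid$n_rows)) {
    sl <- a[, row_block == rb, , drop = FALSE]   # (frame, rows-in-block, col_block)
    s <- colSums(aperm(sl, c(2L, 1L, 3L)))       # (frame, col_block)
    idx <- (rb - 1L) * grid$n_cols + seq_len(grid$n_cols)
    values[idx, ] <- t(s) / npix
  }
  structure(
    list(values = values, grid = grid, frame_rate = stack$frame_rate),
    class = "intensity_traces"
  )
}

#' @export
print.intensity_traces <- function(x, ...) {
  cat(sprintf("<intensity_traces> %d ROIs x %d frames at %.4g fps\n",
              nrow(x$values), ncol(x$values), x$frame_rate))
  invisible(x)
}

#' Export raw ROI traces as CSV
#'
#' One row per ROI: 1-based grid position followed by the intensity at each
#' frame (`roi_row, roi_col, I_t0, I_t1, ...`).
#'
#' @param traces an [extract_traces()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_traces_csv <- function(traces, path) {
  stopifnot(inherits(traces, "intensity_traces"))
  g <- traces$grid
  pos <- expand.grid(roi_col = seq_len(g$n_cols), roi_row = seq_len(g$n_rows))
  df <- data.frame(roi_row = pos$roi_row, roi_col = pos$roi_col,
                   traces$values, check.names = FALSE)
  names(df)[-(1:2)] <- paste0("I_t", seq_len(ncol(traces$values)) - 1L)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
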