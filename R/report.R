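#' Field-level CBF summary report
#'
#' Summarizes a per-ROI CBF map into the statistics a reader of the field
#' cares about: mean, median and modal CBF, the rejection breakdown, a
#' histogram and a grid-shaped heatmap matrix. Statistics are computed over
#' accepted (nonzero) ROIs only: 0 Hz is a rejection label, not a
#' measurement, and averaging it in would bias the field CBF downward. The
#' static fraction is reported as its own headline count instead. Set
#' `include_zeros = TRUE` to reproduce an all-ROI average.
#'
#' @param map a [compute_cbf()] result.
#' @param hist_bin_width histogram bin width in Hz (default 1).
#' @param include_zeros include rejected (0 Hz) ROIs in mean/median/mode.
#' @return An object of class `cbf_report` with fields `mean_cbf`,
#'   `median_cbf`, `modal_cbf`, `sd_cbf` (all `NA` when nothing was
#'   accepted), counts `n_total`, `n_accepted`, `n_static`, `n_below_snr`,
#'   `n_out_of_band`, `histogram` (data frame `bin_low`, `bin_high`,
#'   `count`) and `heatmap` (n_rows x n_cols matrix of CBF values).
#' @examples
#' m <- structure(list(
#'   cbf = c(10, 10, 12, 0, 0),
#'   rejection_reason = c("none", "none", "none", "static", "below_snr"),
#'   grid = make_grid(5, 1, 5, 1), fr = 0.5,
#'   band = band_filter("respiratory"), frame_rate = 250, n_fft = 512),
#'   class = "cbf_map")
#' summarize_cbf(m)
#' @export
summarize_cbf <- function(map, hist_bin_width = 1, include_zeros = FALSE) {
  stopifnot(inherits(map, "cbf_map"), hist_bin_width > 0)
  accepted <- map$cbf[map$rejection_reason == "none"]
  n_total <- length(map$cbf)
  counts <- c(
    n_accepted = sum(map$rejection_reason == "none"),
    n_static = sum(map$rejection_reason == "static"),
    n_below_snr = sum(map$rejection_reason == "below_snr"),
    n_out_of_band = sum(map$rejection_reason == "out_of_band")
  )
  vals <- if (include_zeros) map$cbf else accepted
  if (length(accepted) == 0L && !include_zeros) {
    warning("no ROI was accepted; summary statistics are undefined",
            call. = FALSE)
  }
  if (length(vals)) {
    edges <- seq(0, (max(vals) %/% hist_bin_width + 1) * hist_bin_width,
                 by = hist_bin_width)
    cnt <- table(cut(vals, breaks = edges, right = FALSE,
                     include.lowest = TRUE))
    hist_df <- data.frame(bin_low = edges[-length(edges)],
                          bin_high = edges[-1L],
                          count = as.integer(cnt))
    # modal CBF: midpoint of the most populated bin, lowest bin on ties
    imax <- which.max(hist_df$count)
    modal <- (hist_df$bin_low[imax] + hist_df$bin_high[imax]) / 2
    stats <- c(mean = mean(vals), median = stats::median(vals),
               modal = modal,
               sd = if (length(vals) > 1L) stats::sd(vals) else NA_real_)
  } else {
    hist_df <- data.frame(bin_low = numeric(0), bin_high = numeric(0),
                          count = integer(0))
    stats <- c(mean = NA_real_, median = NA_real_, modal = NA_real_,
               sd = NA_real_)
  }
  heat <- matrix(map$cbf, nrow = map$grid$n_rows, ncol = map$grid$n_cols,
                 byrow = TRUE)
  structure(
    list(mean_cbf = stats[["mean"]], median_cbf = stats[["median"]],
         modal_cbf = stats[["modal"]], sd_cbf = stats[["sd"]],
         n_total = n_total,
         n_accepted = counts[["n_accepted"]],
         n_static = counts[["n_static"]],
         n_below_snr = counts[["n_below_snr"]],
         n_out_of_band = counts[["n_out_of_band"]],
         histogram = hist_df, heatmap = heat,
         hist_bin_width = hist_bin_width, include_zeros = include_zeros),
    class = "cbf_report"
  )
}

#' @export
print.cbf_report <- function(x, ...) {
  cat("<cbf_report>\n")
  if (is.na(x$mean_cbf)) {
    cat("  no accepted ROIs: CBF statistics undefined\n")
  } else {
    cat(sprintf("  mean %.2f Hz, median %.2f Hz, modal %.2f Hz, sd %.2f Hz\n",
                x$mean_cbf, x$median_cbf, x$modal_cbf, x$sd_cbf))
  }
  cat(sprintf("  ROIs: %d total = %d accepted + %d static + %d below SNR + %d out of band\n",
              x$n_total, x$n_accepted, x$n_static, x$n_below_snr,
              x$n_out_of_band))
  invisible(x)
}

#' Direct-counting CBF conversion
#'
#' The reference method: an observer times how many frames elapse during a
#' fixed number of ciliary beat cycles in slow-motion playback, and the
#' frequency is `frame_rate / frames_elapsed * n_beats`.
#'
#' @param frame_rate recording rate in frames per second.
#' @param frames_elapsed frames counted while `n_beats` cycles completed.
#' @param n_beats number of beat cycles timed (conventionally 5).
#' @return Beat frequency in Hz.
#' @examples
#' direct_count_cbf(250, 125)      # 10 Hz
#' direct_count_cbf(500, 62)       # 40.32 Hz
#' @export
direct_count_cbf <- function(frame_rate, frames_elapsed, n_beats = 5) {
  if (!is.numeric(frame_rate) || any(frame_rate <= 0)) {
    stop("`frame_rate` must be > 0", call. = FALSE)
  }
  if (!is.numeric(frames_elapsed) || any(frames_elapsed < 1)) {
    stop("`frames_elapsed` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(n_beats) || any(n_beats < 1)) {
    stop("`n_beats` must be >= 1", call. = FALSE)
  }
  frame_rate / frames_elapsed * n_beats
}

#' Method-agreement statistics for paired CBF measurements
#'
#' Given paired measurements of the same regions by two methods, computes
#' the mean difference, Bland-Altman limits of agreement (mean difference
#' +/- 1.96 x SD of the differences), the coefficient of determination of a
#' least-squares regression of `method_a` on `method_b`, and a paired
#' two-sided t-test.
#'
#' @param method_a,method_b equal-length numeric vectors (Hz), pairwise
#'   measurements of the same regions; `n >= 3`.
#' @return An object of class `cbf_agreement` with `mean_difference`,
#'   `sd_difference`, `loa_low`, `loa_high`, `r_squared`, `t_statistic`,
#'   `p_value`, `n`.
#' @examples
#' a <- c(10, 12, 14, 16); agreement(a, a + 0.5)
#' @export
agreement <- function(method_a, method_b) {
  if (length(method_a) != length(method_b)) {
    stop("paired measurements must have equal length", call. = FALSE)
  }
  n <- length(method_a)
  if (n < 3L) stop("agreement needs at least 3 pairs", call. = FALSE)
  d <- method_a - method_b
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd > 0) {
    tt <- stats::t.test(method_a, method_b, paired = TRUE)
    t_stat <- unname(tt$statistic); p_val <- tt$p.value
  } else {
    # identical differences everywhere: t is 0/0 (md = 0) or infinite
    t_stat <- if (md == 0) 0 else sign(md) * Inf
    p_val <- if (md == 0) 1 else 0
  }
  r2 <- if (stats::var(method_b) > 0 && stats::var(method_a) > 0) {
    stats::cor(method_a, method_b)^2
  } else if (sdd == 0) 1 else NA_real_
  structure(
    list(mean_difference = md, sd_difference = sdd,
         loa_low = md - 1.96 * sdd, loa_high = md + 1.96 * sdd,
         r_squared = r2, t_statistic = t_stat, p_value = p_val, n = n),
    class = "cbf_agreement"
  )
}

#' @export
print.cbf_agreement <- function(x, ...) {
  cat(sprintf(
    "<cbf_agreement> n = %d: mean diff %.3f +/- %.3f Hz, LoA [%.2f, %.2f], r^2 = %.4f, t = %.3f (p = %.3g)\n",
    x$n, x$mean_difference, x$sd_difference, x$loa_low, x$loa_high,
    x$r_squared, x$t_statistic, x$p_value))
  invisible(x)
}

#' Export a CBF report to CSV files and a heatmap image
#'
#' Writes four artifacts into `out_dir`, named after `prefix`:
#' `<prefix>_rois.csv` (`roi_row, roi_col, cbf_hz, reason`),
#' `<prefix>_summary.csv`, `<prefix>_histogram.csv`, and
#' `<prefix>_heatmap.png` (darker cell = higher CBF; rejected ROIs are
#' white). File contents are deterministic for identical inputs.
#'
#' @param report a [summarize_cbf()] result.
#' @param map the [compute_cbf()] result the report came from.
#' @param out_dir output directory (created if missing).
#' @param prefix file-name prefix (default `"cbf"`).
#' @param heatmap write the PNG heatmap (requires a functional png device).
#' @return Named character vector of the files written, invisibly.
#' @export
export_report <- function(report, map, out_dir, prefix = "cbf",
                          heatmap = TRUE) {
  stopifnot(inherits(report, "cbf_report"), inherits(map, "cbf_map"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  g <- map$grid
  pos <- expand.grid(roi_col = seq_len(g$n_cols), roi_row = seq_len(g$n_rows))
  roi_df <- data.frame(roi_row = pos$roi_row, roi_col = pos$roi_col,
                       cbf_hz = map$cbf, reason = map$rejection_reason)
  files <- c(rois = file.path(out_dir, paste0(prefix, "_rois.csv")),
             summary = file.path(out_dir, paste0(prefix, "_summary.csv")),
             histogram = file.path(out_dir, paste0(prefix, "_histogram.csv")))
  utils::write.csv(roi_df, files[["rois"]], row.names = FALSE)
  summary_df <- data.frame(
    statistic = c("mean_cbf_hz", "median_cbf_hz", "modal_cbf_hz", "sd_cbf_hz",
                  "n_total", "n_accepted", "n_static", "n_below_snr",
                  "n_out_of_band", "frequency_resolution_hz",
                  "band_low_hz", "band_high_hz"),
    value = c(round(report$mean_cbf, 2), round(report$median_cbf, 2),
              round(report$modal_cbf, 2), round(report$sd_cbf, 2),
              report$n_total, report$n_accepted, report$n_static,
              report$n_below_snr, report$n_out_of_band,
              map$fr, map$band$f_min, map$band$f_max)
  )
  utils::write.csv(summary_df, files[["summary"]], row.names = FALSE)
  utils::write.csv(report$histogram, files[["histogram"]], row.names = FALSE)
  if (heatmap && capabilities("png")) {
    png_path <- file.path(out_dir, paste0(prefix, "_heatmap.png"))
    grDevices::png(png_path, width = 480, height = 480)
    on.exit(grDevices::dev.off(), add = TRUE)
    hm <- report$heatmap
    # darker = higher CBF; plot row 1 at the top
    z <- t(hm[rev(seq_len(nrow(hm))), , drop = FALSE])
    top <- max(hm, map$band$f_max)
    graphics::image(x = seq_len(ncol(hm)), y = seq_len(nrow(hm)), z = z,
                    zlim = c(0, top),
                    col = grDevices::gray(seq(1, 0, length.out = 256)),
                    xlab = "ROI column", ylab = "ROI row",
                    main = "CBF heatmap (darker = higher)", useRaster = TRUE)
    files <- c(files, heatmap = png_path)
  }
  invisible(files)
}

#' Read paired CBF measurements from a CSV file
#'
#' Expects a numeric column named `cbf_hz` (or uses the first numeric
#' column). Helper for the command-line agreement utility.
#'
#' @param path CSV path.
#' @return Numeric vector of CBF values in Hz.
#' @export
read_cbf_csv <- function(path) {
  df <- utils::read.csv(path)
  col <- if ("cbf_hz" %in% names(df)) "cbf_hz" else {
    num <- vapply(df, is.numeric, logical(1))
    if (!any(num)) stop("no numeric CBF column in ", path, call. = FALSE)
    names(df)[which(num)[1L]]
  }
  df[[col]]
}
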