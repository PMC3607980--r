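#' Spectral frequency resolution
#'
#' The spacing between frequency bins of the magnitude spectrum:
#' `frame_rate / n_frames` (Hz). Each spectral bin `k` maps to frequency
#' `k * FR`, so FR bounds the precision of any single-bin frequency
#' estimate. Recording more frames at a fixed frame rate lowers FR and
#' improves accuracy; spatial cropping leaves it untouched.
#'
#' @param frame_rate acquisition rate in Hz, `> 0`.
#' @param n_frames number of frames transformed, `>= 2`.
#' @return Frequency resolution in Hz.
#' @examples
#' frequency_resolution(120, 128)   # 0.9375 Hz
#' frequency_resolution(250, 512)   # ~0.488 Hz
#' @export
frequency_resolution <- function(frame_rate, n_frames) {
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    stop("`frame_rate` must be > 0", call. = FALSE)
  }
  if (!is.numeric(n_frames) || n_frames < 2) {
    stop("`n_frames` must be >= 2", call. = FALSE)
  }
  frame_rate / n_frames
}

#' Frequency band filter for clinically relevant CBF ranges
#'
#' @param preset `"respiratory"` (3--20 Hz, the usual range for airway
#'   cilia), `"ependymal"` (3--60 Hz, brain ependymal cilia beat much
#'   faster), or `"custom"` with explicit `f_min`/`f_max`.
#' @param f_min,f_max band edges in Hz for `preset = "custom"`.
#' @return An object of class `band_filter` with `f_min`, `f_max`, `preset`.
#' @export
band_filter <- function(preset = c("respiratory", "ependymal", "custom"),
                        f_min = NULL, f_max = NULL) {
  preset <- match.arg(preset)
  if (preset == "respiratory") { f_min <- 3; f_max <- 20 }
  if (preset == "ependymal")   { f_min <- 3; f_max <- 60 }
  if (is.null(f_min) || is.null(f_max)) {
    stop("custom band needs both `f_min` and `f_max`", call. = FALSE)
  }
  if (!(f_min > 0 && f_max > f_min)) {
    stop("band must satisfy 0 < f_min < f_max", call. = FALSE)
  }
  structure(list(f_min = as.numeric(f_min), f_max = as.numeric(f_max),
                 preset = preset),
            class = "band_filter")
}

.largest_pow2 <- function(n) 2L^floor(log2(n))

#' Magnitude spectra of ROI intensity traces
#'
#' Per ROI: the trace mean is subtracted (DC removal), the trace is cut to
#' the transform length dictated by `n_fft_policy`, the discrete Fourier
#' transform is taken, and the complex modulus of coefficients
#' `k = 0 .. n_fft/2` is stored. No window is applied by default
#' (rectangular), matching a plain spreadsheet-style FFT; a Hann window is
#' available for signals suffering from spectral leakage.
#'
#' @param traces an [extract_traces()] result (or any `intensity_traces`).
#' @param n_fft_policy `"pow2"` truncates each trace to the largest power of
#'   two not exceeding its length (the classic FFT restriction); `"full"`
#'   transforms the whole trace.
#' @param window `"rectangular"` (default) or `"hann"`.
#' @return An object of class `spectrum_set`: `magnitudes` (ROI x bin
#'   matrix, bins `k = 0 .. n_fft/2`), `fr` (frequency resolution, Hz),
#'   `n_fft`, `frame_rate`, `grid`.
#' @export
compute_spectrum <- function(traces, n_fft_policy = c("pow2", "full"),
                             window = c("rectangular", "hann")) {
  stopifnot(inherits(traces, "intensity_traces"))
  n_fft_policy <- match.arg(n_fft_policy)
  window <- match.arg(window)
  len <- ncol(traces$values)
  if (len < 4L) stop("traces must have at least 4 frames for spectral ",
                     "analysis, got ", len, call. = FALSE)
  n_fft <- if (n_fft_policy == "pow2") .largest_pow2(len) else len
  x <- traces$values[, seq_len(n_fft), drop = FALSE]
  x <- x - rowMeans(x)
  if (window == "hann") {
    # periodic Hann: w_t = 0.5 (1 - cos(2 pi t / N)), t = 0 .. N-1
    w <- 0.5 * (1 - cos(2 * pi * (seq_len(n_fft) - 1L) / n_fft))
    x <- sweep(x, 2L, w, `*`)
  }
  co <- stats::mvfft(t(x))                      # frames x ROI, complex
  half <- n_fft %/% 2L
  mags <- t(Mod(co[seq_len(half + 1L), , drop = FALSE]))
  structure(
    list(magnitudes = mags,
         fr = traces$frame_rate / n_fft,
         n_fft = n_fft,
         frame_rate = traces$frame_rate,
         grid = traces$grid),
    class = "spectrum_set"
  )
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d ROIs, n_fft = %d, FR = %.5g Hz\n",
              nrow(x$magnitudes), x$n_fft, x$fr))
  invisible(x)
}

#' Dominant spectral peak within a frequency band
#'
#' Returns the bin with maximal magnitude among bins whose frequency
#' `k * fr` lies inside `[f_min, f_max]`; ties break toward the lower bin.
#'
#' @param magnitudes numeric vector of spectral magnitudes for bins
#'   `k = 0 .. n/2` (element `i` is bin `i - 1`).
#' @param band a [band_filter()].
#' @param fr frequency resolution in Hz.
#' @return List with `peak_bin` (0-based bin index) and `peak_mag`.
#' @export
dominant_peak <- function(magnitudes, band, fr) {
  stopifnot(inherits(band, "band_filter"), fr > 0)
  k <- seq_along(magnitudes) - 1L
  in_band <- which(k * fr >= band$f_min & k * fr <= band$f_max)
  if (!length(in_band)) {
    stop(sprintf(
      "band [%.3g, %.3g] Hz contains no spectral bin at FR = %.5g Hz",
      band$f_min, band$f_max, fr), call. = FALSE)
  }
  i <- in_band[which.max(magnitudes[in_band])]   # which.max: first max wins
  list(peak_bin = k[i], peak_mag = magnitudes[i])
}

#' Flanking-peak frequency refinement
#'
#' Sub-bin frequency estimate: the magnitude-weighted mean frequency over
#' the dominant bin and its two immediate neighbours,
#' `sum(k * fr * m_k) / sum(m_k)` for `k` in `{peak - 1, peak, peak + 1}`.
#' For a peak with symmetric flanks this reduces to the raw bin frequency;
#' for an off-bin sinusoid the leakage asymmetry pulls the estimate toward
#' the true frequency. Missing flanks at the spectrum edges count as zero
#' magnitude.
#'
#' @param magnitudes numeric vector of magnitudes, bins `k = 0 .. n/2`.
#' @param peak_bin 0-based dominant bin index.
#' @param fr frequency resolution in Hz.
#' @return Refined frequency estimate in Hz.
#' @export
flanking_average <- function(magnitudes, peak_bin, fr) {
  n <- length(magnitudes)
  ks <- peak_bin + (-1L:1L)
  m <- numeric(3L)
  ok <- ks >= 0L & ks <= n - 1L
  m[ok] <- magnitudes[ks[ok] + 1L]
  tot <- sum(m)
  if (tot <= 0) return(peak_bin * fr)
  sum(ks * fr * m) / tot
}

#' Noise-rejection screen for a spectral peak
#'
#' A candidate peak is accepted only when (1) its magnitude exceeds
#' `snr_factor` times the background, defined as the maximum of the first
#' three non-DC magnitudes (bins 1--3; with the mean removed these bins
#' carry only slow drift), and (2) its frequency lies inside the clinically
#' relevant band. Spectra that are essentially zero everywhere (static
#' regions) are flagged separately.
#'
#' @param magnitudes numeric vector of DC-removed magnitudes, bins
#'   `k = 0 .. n/2`.
#' @param peak_bin 0-based dominant bin index.
#' @param peak_freq candidate frequency in Hz (after flanking refinement).
#' @param band a [band_filter()].
#' @param snr_factor required peak-to-background ratio (default 3).
#' @param static_tol absolute magnitude below which a whole spectrum counts
#'   as static.
#' @return One of `"none"`, `"below_snr"`, `"out_of_band"`, `"static"`.
#' @export
noise_reject <- function(magnitudes, peak_bin, peak_freq, band,
                         snr_factor = 3, static_tol = 1e-8) {
  stopifnot(inherits(band, "band_filter"))
  non_dc <- magnitudes[-1L]
  if (!length(non_dc) || max(non_dc) <= static_tol) return("static")
  background <- max(magnitudes[2:min(4L, length(magnitudes))])  # bins 1..3
  peak_mag <- magnitudes[peak_bin + 1L]
  if (peak_mag <= snr_factor * background) return("below_snr")
  if (peak_freq < band$f_min || peak_freq > band$f_max) return("out_of_band")
  "none"
}

#' Per-ROI ciliary beat frequency map
#'
#' The full estimation chain for every ROI: magnitude spectrum, dominant
#' in-band peak, noise rejection, and flanking-peak refinement. Rejected or
#' static ROIs are assigned exactly 0 Hz together with a rejection reason;
#' 0 Hz is a label ("no credible beat measured here"), not a measurement.
#'
#' @param traces an [extract_traces()] result.
#' @param band a [band_filter()] (default respiratory, 3--20 Hz).
#' @param snr_factor peak-to-background acceptance ratio (default 3).
#' @param n_fft_policy,window passed to [compute_spectrum()].
#' @param peak_mode frequency refinement: `"centroid"` (default,
#'   [flanking_average()]), `"mean3"` (unweighted mean of the three bin
#'   frequencies), or `"raw"` (peak bin frequency, no refinement).
#' @return An object of class `cbf_map`: `cbf` (numeric vector, Hz, 0 =
#'   rejected), `rejection_reason` (character vector), `grid`, `fr`,
#'   `band`, `frame_rate`, `n_fft`.
#' @examples
#' spec <- synthetic_spec(frame_rate = 250, n_frames = 256, height = 20,
#'   width = 20, regions = list(synthetic_region(1, 1, 20, 20, frequency = 12)))
#' tr <- extract_traces(generate_video(spec)$stack, make_grid(20, 20, 2, 2))
#' compute_cbf(tr)$cbf
#' @export
compute_cbf <- function(traces, band = band_filter("respiratory"),
                        snr_factor = 3,
                        n_fft_policy = c("pow2", "full"),
                        window = c("rectangular", "hann"),
                        peak_mode = c("centroid", "mean3", "raw")) {
  peak_mode <- match.arg(peak_mode)
  ss <- compute_spectrum(traces, n_fft_policy = n_fft_policy, window = window)
  n_roi <- nrow(ss$magnitudes)
  cbf <- numeric(n_roi)
  reason <- character(n_roi)
  for (i in seq_len(n_roi)) {
    mags <- ss$magnitudes[i, ]
    pk <- dominant_peak(mags, band, ss$fr)
    est <- switch(peak_mode,
      centroid = flanking_average(mags, pk$peak_bin, ss$fr),
      mean3 = {
        ks <- pk$peak_bin + (-1L:1L)
        ks <- ks[ks >= 0L & ks <= length(mags) - 1L]
        mean(ks) * ss$fr
      },
      raw = pk$peak_bin * ss$fr
    )
    rej <- noise_reject(mags, pk$peak_bin, est, band, snr_factor = snr_factor)
    if (rej == "none") {
      cbf[i] <- est
      reason[i] <- "none"
    } else {
      cbf[i] <- 0
      reason[i] <- rej
    }
  }
  structure(
    list(cbf = cbf, rejection_reason = reason, grid = ss$grid,
         fr = ss$fr, band = band, frame_rate = ss$frame_rate,
         n_fft = ss$n_fft),
    class = "cbf_map"
  )
}

#' @export
print.cbf_map <- function(x, ...) {
  acc <- sum(x$rejection_reason == "none")
  cat(sprintf(
    "<cbf_map> %d ROIs: %d accepted, %d rejected; FR = %.4g Hz, band [%g, %g] Hz\n",
    length(x$cbf), acc, length(x$cbf) - acc, x$fr, x$band$f_min, x$band$f_max))
  if (acc > 0) {
    cat(sprintf("  accepted CBF: mean %.2f Hz, range [%.2f, %.2f] Hz\n",
                mean(x$cbf[x$cbf > 0]), min(x$cbf[x$cbf > 0]),
                max(x$cbf[x$cbf > 0])))
  }
  invisible(x)
}

#' Export a per-ROI spectrum as CSV
#'
#' Columns `bin`, `frequency_hz`, `magnitude` for one ROI, mirroring the
#' inspectable per-region power spectrum of the original spreadsheet report.
#'
#' @param spectra a [compute_spectrum()] result.
#' @param roi 1-based ROI index (row-major).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_spectrum_csv <- function(spectra, roi, path) {
  stopifnot(inherits(spectra, "spectrum_set"),
            roi >= 1, roi <= nrow(spectra$magnitudes))
  k <- seq_len(ncol(spectra$magnitudes)) - 1L
  utils::write.csv(
    data.frame(bin = k, frequency_hz = k * spectra$fr,
               magnitude = spectra$magnitudes[roi, ]),
    path, row.names = FALSE)
  invisible(path)
}
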