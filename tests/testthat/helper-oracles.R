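# Independent oracles and fixture builders. The DFT oracle deliberately
# avoids stats::fft: it evaluates the definition directly in O(N^2) so it
# can stand against the implementation's FFT path.

# magnitudes |X_k| for k = 0 .. N/2 by direct summation
dft_mag_oracle <- function(x) {
  n <- length(x)
  t <- seq_len(n) - 1L
  vapply(0:(n %/% 2L), function(k) {
    Mod(sum(x * exp(-2i * pi * k * t / n)))
  }, numeric(1))
}

# stack whose every pixel follows a given time signal
signal_stack <- function(signal, height = 4L, width = 4L, frame_rate = 250) {
  nf <- length(signal)
  frame_stack(array(rep(signal, height * width), c(nf, height, width)),
              frame_rate)
}

# intensity_traces straight from a matrix (ROI x frame), bypassing video
traces_from_matrix <- function(values, frame_rate = 250) {
  g <- make_grid(nrow(values), 1L, nrow(values), 1L)
  structure(list(values = values, grid = g, frame_rate = frame_rate),
            class = "intensity_traces")
}

# cbf_map from bare values, for report-level tests
map_from_values <- function(cbf, n_rows = length(cbf), n_cols = 1L,
                            fr = 0.5, band = band_filter("ependymal")) {
  reason <- ifelse(cbf > 0, "none", "static")
  structure(list(cbf = cbf, rejection_reason = reason,
                 grid = make_grid(n_rows, n_cols, n_rows, n_cols),
                 fr = fr, band = band, frame_rate = 250, n_fft = 512),
            class = "cbf_map")
}

# single oscillating full-frame region, noiseless unless stated
osc_spec <- function(frequency, frame_rate = 250, n_frames = 512,
                     height = 40, width = 40, amplitude = 60,
                     baseline = 120, noise_sd = 0, seed = 1L, ...) {
  synthetic_spec(
    frame_rate = frame_rate, n_frames = n_frames,
    height = height, width = width,
    regions = list(synthetic_region(1, 1, width, height,
                                    frequency = frequency,
                                    amplitude = amplitude,
                                    baseline = baseline)),
    noise_sd = noise_sd, seed = seed, ...)
}
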