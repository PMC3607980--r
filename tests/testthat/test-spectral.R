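test_that("frequency_resolution is frame_rate / n_frames with validation", {
  expect_equal(frequency_resolution(120, 128), 0.9375)  # prints as 0.94
  expect_equal(frequency_resolution(250, 512), 0.48828125)
  expect_equal(frequency_resolution(500, 1024), 0.48828125)
  expect_error(frequency_resolution(0, 128), "> 0")
  expect_error(frequency_resolution(120, 1), ">= 2")
})

test_that("band presets carry the clinical ranges and validate edges", {
  b <- band_filter("respiratory")
  expect_equal(c(b$f_min, b$f_max), c(3, 20))
  e <- band_filter("ependymal")
  expect_equal(c(e$f_min, e$f_max), c(3, 60))
  expect_equal(band_filter("custom", 5, 15)$f_max, 15)
  expect_error(band_filter("custom", 10, 5), "f_min < f_max")
  expect_error(band_filter("custom", 5), "f_min.*f_max|f_max")
})

test_that("spectra match the brute-force DFT oracle after DC removal", {
  set.seed(31)
  for (n in c(16L, 200L, 256L)) {
    x <- runif(n, 0, 255)
    tr <- traces_from_matrix(matrix(x, 1), frame_rate = 250)
    ss <- compute_spectrum(tr, n_fft_policy = "full")
    expect_equal(ss$n_fft, n)
    oracle <- dft_mag_oracle(x - mean(x))
    expect_equal(ss$magnitudes[1, ], oracle, tolerance = 1e-9)
    # pow2 policy truncates, then removes the mean of the truncated piece
    ss2 <- compute_spectrum(tr, n_fft_policy = "pow2")
    n2 <- 2^floor(log2(n))
    expect_equal(ss2$n_fft, n2)
    expect_equal(ss2$fr, 250 / n2)
    expect_equal(ss2$magnitudes[1, ],
                 dft_mag_oracle(x[1:n2] - mean(x[1:n2])), tolerance = 1e-9)
  }
  expect_error(compute_spectrum(traces_from_matrix(matrix(1:3, 1))),
               "at least 4")
})

test_that("constant traces transform to zero; on-bin sinusoids to N*A/2", {
  tr <- traces_from_matrix(matrix(42, 1, 64))
  expect_equal(max(compute_spectrum(tr)$magnitudes), 0)

  n <- 128L; A <- 3.5; k0 <- 20L
  x <- 100 + A * sin(2 * pi * k0 * (0:(n - 1)) / n)
  ss <- compute_spectrum(traces_from_matrix(matrix(x, 1), 250))
  mags <- ss$magnitudes[1, ]
  expect_equal(mags[k0 + 1], n * A / 2, tolerance = 1e-9)
  expect_lt(max(mags[-(k0 + 1)]), 1e-8)
})

test_that("hann window halves the on-bin peak and is otherwise benign", {
  n <- 128L
  x <- 10 * sin(2 * pi * 16 * (0:(n - 1)) / n)
  tr <- traces_from_matrix(matrix(x, 1), 250)
  m_rect <- compute_spectrum(tr)$magnitudes[1, ]
  m_hann <- compute_spectrum(tr, window = "hann")$magnitudes[1, ]
  expect_equal(m_hann[17], m_rect[17] / 2, tolerance = 1e-9)
})

test_that("dominant_peak takes the in-band maximum, lower bin on ties", {
  fr <- 0.5
  mags <- rep(1, 101)                      # bins 0..100 -> 0..50 Hz
  mags[25] <- 9                            # bin 24 = 12 Hz
  pk <- dominant_peak(mags, band_filter("respiratory"), fr)
  expect_identical(pk$peak_bin, 24L)
  expect_equal(pk$peak_mag, 9)

  mags2 <- rep(0.1, 101); mags2[c(11, 31)] <- 5   # bins 10 and 30 tie
  expect_identical(
    dominant_peak(mags2, band_filter("ependymal"), fr)$peak_bin, 10L)

  # band excludes the global max: in-band winner is returned
  mags3 <- rep(0.1, 101); mags3[3] <- 100; mags3[21] <- 2
  expect_identical(
    dominant_peak(mags3, band_filter("respiratory"), fr)$peak_bin, 20L)

  expect_error(dominant_peak(rep(1, 5), band_filter("ependymal"), 0.5),
               "no spectral bin")
})

test_that("dominant_peak agrees with brute-force search for a 42 Hz sinusoid", {
  # 500 fps, 512 frames -> fr = 0.9765625; truth 42 Hz sits nearest bin 43
  fps <- 500; n <- 512L; fr <- fps / n
  x <- 120 + 50 * sin(2 * pi * 42 * (0:(n - 1)) / fps)
  oracle <- dft_mag_oracle(x - mean(x))
  band <- band_filter("ependymal")
  k <- 0:(n / 2)
  in_band <- which(k * fr >= band$f_min & k * fr <= band$f_max)
  brute_bin <- k[in_band][which.max(oracle[in_band])]
  expect_identical(brute_bin, 43L)

  ss <- compute_spectrum(traces_from_matrix(matrix(x, 1), fps))
  pk <- dominant_peak(ss$magnitudes[1, ], band, ss$fr)
  expect_identical(pk$peak_bin, brute_bin)
  expect_equal(pk$peak_bin * ss$fr, 41.9922, tolerance = 1e-4)
})

test_that("flanking_average implements the weighted three-bin centroid", {
  fr <- 0.5
  m <- rep(0, 61)
  m[c(20, 21, 22)] <- c(2, 10, 2)          # symmetric flanks -> k * fr
  expect_equal(flanking_average(m, 20L, fr), 20 * fr)
  m2 <- rep(0, 61); m2[21] <- 10; m2[22] <- 10   # m_{k-1}=0, m_{k+1}=m_k
  expect_equal(flanking_average(m2, 20L, fr), 20.5 * fr)
  # edges clamp: missing flank counts as zero magnitude
  m3 <- rep(0, 61); m3[1] <- 4; m3[2] <- 4
  expect_equal(flanking_average(m3, 0L, fr), (0 * 4 + 1 * 4) / 8 * fr)
  m4 <- rep(0, 61); m4[61] <- 6
  expect_equal(flanking_average(m4, 60L, fr), 60 * fr)
  # all-zero neighborhood: fall back to the raw bin frequency
  expect_equal(flanking_average(rep(0, 61), 30L, fr), 30 * fr)
})

test_that("off-bin sinusoid: centroid lands within fr/2 and beats the raw bin", {
  fps <- 250; n <- 512L; fr <- fps / n     # 10 Hz falls between bins 20, 21
  x <- 120 + 40 * sin(2 * pi * 10 * (0:(n - 1)) / fps)
  mags <- dft_mag_oracle(x - mean(x))
  band <- band_filter("respiratory")
  pk <- dominant_peak(mags, band, fr)
  est <- flanking_average(mags, pk$peak_bin, fr)
  expect_lt(abs(est - 10), fr / 2)
  expect_lt(abs(est - 10), abs(pk$peak_bin * fr - 10))
})

test_that("noise_reject applies the 3x background rule, band, and static screen", {
  band <- band_filter("respiratory")
  expect_identical(noise_reject(rep(0, 40), 10L, 5, band), "static")

  mags <- rep(0, 40)
  mags[2:4] <- c(10, 8, 6)                 # background = 10 (max of bins 1..3)
  mags[21] <- 29                           # 2.9x -> rejected
  expect_identical(noise_reject(mags, 20L, 10, band), "below_snr")
  mags[21] <- 31                           # 3.1x -> accepted
  expect_identical(noise_reject(mags, 20L, 10, band), "none")
  expect_identical(noise_reject(mags, 20L, 10, band, snr_factor = 4),
                   "below_snr")
  # strong but out-of-band candidate (e.g. a 2 Hz sinusoid's frequency)
  expect_identical(noise_reject(mags, 20L, 2, band), "out_of_band")
  expect_identical(noise_reject(mags, 20L, 25, band), "out_of_band")
  # DC magnitude never counts as background
  mags[1] <- 1e6
  expect_identical(noise_reject(mags, 20L, 10, band), "none")
})

test_that("compute_cbf recovers region frequencies and labels static ROIs", {
  # half the field oscillates at 12 Hz, half is static
  spec <- synthetic_spec(
    frame_rate = 250, n_frames = 512, height = 40, width = 40,
    regions = list(
      synthetic_region(1, 1, 40, 20, frequency = 12, amplitude = 50,
                       baseline = 120),
      synthetic_region(1, 21, 40, 20, frequency = 0, amplitude = 0,
                       baseline = 120)))
  out <- generate_video(spec)
  tr <- extract_traces(out$stack, make_grid(40, 40, 4, 4))
  m <- compute_cbf(tr)
  osc <- 1:8; static <- 9:16               # row-major: top 2 ROI rows oscillate
  expect_true(all(m$rejection_reason[osc] == "none"))
  expect_true(all(abs(m$cbf[osc] - 12) <= m$fr))
  expect_true(all(m$rejection_reason[static] == "static"))
  expect_true(all(m$cbf[static] == 0))
  # 0 Hz <=> rejected, and accepted values stay within the widened band
  expect_identical(m$cbf == 0, m$rejection_reason != "none")
  nz <- m$cbf[m$cbf > 0]
  expect_true(all(nz >= m$band$f_min - m$fr & nz <= m$band$f_max + m$fr))
})

test_that("peak_mode variants stay within one bin of each other on clean input", {
  out <- generate_video(osc_spec(11.3, height = 20, width = 20))
  tr <- extract_traces(out$stack, make_grid(20, 20, 2, 2))
  est <- vapply(c("centroid", "mean3", "raw"), function(pm) {
    compute_cbf(tr, peak_mode = pm)$cbf[1]
  }, numeric(1))
  fr <- 250 / 512
  expect_true(all(abs(est - 11.3) <= fr))
  expect_lt(abs(est[["centroid"]] - 11.3), abs(est[["raw"]] - 11.3))
})

test_that("two disjoint regions do not cross-talk", {
  spec <- synthetic_spec(
    frame_rate = 250, n_frames = 512, height = 40, width = 40,
    regions = list(
      synthetic_region(1, 1, 40, 20, frequency = 8, amplitude = 50,
                       baseline = 120),
      synthetic_region(1, 21, 40, 20, frequency = 15, amplitude = 50,
                       baseline = 120)))
  out <- generate_video(spec)
  m <- compute_cbf(extract_traces(out$stack, make_grid(40, 40, 4, 4)))
  fr <- m$fr
  expect_true(all(abs(m$cbf[1:8] - 8) <= fr))
  expect_true(all(abs(m$cbf[9:16] - 15) <= fr))
})

test_that("doubling the frame count halves FR and does not worsen recovery", {
  for (f in c(7.3, 13.9)) {
    errs <- vapply(c(256L, 512L, 1024L), function(nf) {
      out <- generate_video(osc_spec(f, n_frames = nf, height = 10, width = 10))
      m <- compute_cbf(extract_traces(out$stack, make_grid(10, 10, 1, 1)))
      c(m$fr, abs(m$cbf[1] - f))
    }, numeric(2))
    expect_equal(errs[1, 1] / 2, errs[1, 2])
    expect_equal(errs[1, 2] / 2, errs[1, 3])
    expect_true(all(errs[2, ] <= errs[1, ]))   # error within one bin always
  }
})

test_that("spectrum CSV export exposes bin, frequency and magnitude", {
  out <- generate_video(osc_spec(10, n_frames = 64, height = 8, width = 8))
  ss <- compute_spectrum(extract_traces(out$stack, make_grid(8, 8, 2, 2)))
  f <- withr::local_tempfile(fileext = ".csv")
  export_spectrum_csv(ss, 3, f)
  df <- read.csv(f)
  expect_identical(names(df), c("bin", "frequency_hz", "magnitude"))
  expect_equal(nrow(df), 33)               # bins 0..32 for n_fft = 64
  expect_equal(df$frequency_hz, df$bin * ss$fr)
  expect_equal(df$magnitude, ss$magnitudes[3, ])
})
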