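---
title: "Measuring ciliary beat frequency from high-speed video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ciliary beat frequency from high-speed video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliafreq)
```

## The measurement problem

Motile cilia on respiratory epithelium beat at roughly 10–14 Hz; ependymal
cilia lining the brain ventricles beat at around 40 Hz. Beat frequency (CBF)
is a core readout in primary ciliary dyskinesia work-ups and in studies of
how temperature, viscosity, toxins or infection alter mucociliary
clearance. The reference method — an observer timing a fixed number of beat
cycles during slow-motion playback of a high-speed recording — is accurate
but extremely slow, and it samples only the regions the observer chooses to
look at.

`ciliafreq` automates the measurement. Light passing a beating cilium
flickers at the beat frequency, so the mean pixel intensity of a small
image patch oscillates with the cilia inside it. The pipeline is:

1. **ROI grid** — each frame is tiled with up to 40 × 40 equal rectangular
   regions of interest (≤ 1600 regions).
2. **Traces** — the mean intensity of each ROI per frame gives one time
   series per region.
3. **Spectrum** — each trace is mean-subtracted and Fourier-transformed;
   the magnitude `|X_k|` at bin `k` corresponds to frequency `k · FR`,
   where the *frequency resolution* is `FR = frame rate / n_frames`.
4. **Peak refinement** — the dominant in-band bin is refined by the
   magnitude-weighted centroid of the bin and its two flanking neighbours,
   recovering sub-bin accuracy for frequencies that fall between bins.
5. **Noise rejection** — a peak is kept only if it exceeds 3× the
   background (the largest of the first three non-DC magnitudes) and lies
   in a clinically relevant band. Everything else — including genuinely
   static cilia — is reported as **0 Hz with a rejection reason**, never as
   a fabricated frequency.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| frame rate | from AVI metadata or user | acquisition rate (Hz); 120 fps is the floor for valid data, 250–500 fps is typical |
| frames transformed | largest power of two ≤ length | sets `FR = fps / n`; 512 frames at 250 fps give `FR ≈ 0.49` Hz, the shortest defensible recording (128 frames at 120 fps) gives `FR = 0.94` Hz |
| grid | largest feasible up to 40 × 40 | smaller ROIs localize better but carry less light; 10 × 10 px is a good compromise at ×40 magnification |
| band | respiratory, 3–20 Hz | `ependymal` (3–60 Hz) for brain preparations; custom bands allowed |
| `snr_factor` | 3 | peak-to-background acceptance ratio; raising it trades sensitivity for specificity |
| `peak_mode` | `centroid` | `mean3` (unweighted three-bin mean) and `raw` (no refinement) exist for comparison |
| window | rectangular | a Hann window is available when spectral leakage from strong neighbours is a problem |

Spatial **cropping** never changes `FR` — it only discards pixels — so it
is a free speed-up on large fields. Temporal truncation does change `FR`.

## Numerical choices

* **DC removal.** The trace mean is subtracted before the FFT. The
  background is then "the maximum of bins 1–3", which is well defined:
  with the mean removed those bins hold only slow drift. The DC bin itself
  is never eligible as peak or background (a spreadsheet-style FFT of a
  raw trace would have its first magnitude dominated by mean brightness,
  and a background defined on it would reject nearly everything).
* **Flanking average.** "Average the peaks flanking the maximum" admits
  two readings; we use the magnitude-weighted centroid
  `Σ k·FR·m_k / Σ m_k` over `{k−1, k, k+1}`. It reduces to the raw bin
  frequency when the flanks are symmetric, and on off-bin sinusoids it is
  strictly more accurate than the raw bin (this is asserted in the test
  suite). The unweighted reading is available as `peak_mode = "mean3"`.
* **Edges and ties.** Ties in the in-band maximum break toward the lower
  bin (deterministic and conservative); missing flanks at the spectrum
  edges count as zero magnitude.
* **Power-of-two truncation.** The default `n_fft` policy truncates each
  trace to the largest power of two ≤ its length, matching how such
  recordings are conventionally transformed; `n_fft_policy = "full"`
  transforms everything.
* **Static detection.** A spectrum whose non-DC magnitudes never exceed
  `1e-8` is labelled `static` — a constant 8-bit trace is exactly zero
  after DC removal, so this threshold only has to absorb floating-point
  noise.
* **Band-edge behaviour.** A signal within one bin of the band edge can
  have its true peak bin *outside* the band (e.g. a 3 Hz tone at
  `FR = 0.98` Hz peaks at 2.93 Hz). The pipeline then either locks onto
  the in-band flank or rejects the region; it never reports a frequency
  far from the truth. Record long enough that `FR` is small relative to
  the distance of your expected CBF from the band edges.

## The synthetic world

Because real validation recordings cannot be shipped, the package carries
a simulator (`synthetic_spec()`, `generate_video()`): rectangular regions
oscillate as sine, sawtooth or square waves (the non-sinusoidal shapes
carry the harmonics real ciliary traces have) on top of a baseline, with
optional i.i.d. Gaussian pixel noise and an optional global "bulb flicker"
modulation. Defaults mirror recording practice: 250 fps, 512 frames, 8-bit
intensities around a baseline of 120 with amplitude ≈ 50.

What the simulator **does not** emulate: metachronal phase waves, optical
blur and depth-of-focus effects, correlated (non-white) camera noise,
motion of the preparation, and partially filled ROIs at region borders. A
green recovery test therefore establishes that the estimator chain is
correct and unbiased for well-behaved periodic signals across 3–52 Hz — it
does not certify performance on poorly focused or drifting recordings.

One acceptance property deserves honesty: the "noise-only videos reject
≥ 95 % of ROIs" check. The 3× rule's false-accept rate on white noise is
about 5–6 % per ROI at default settings (respiratory band, 512-point
spectra — 34 candidate bins against a background of 3), so the expected
rejection is ~94–95 %: the criterion sits at the edge of the rule's own
behaviour. The test pools 1200 ROIs over three fixed seeds and passes at
95.25 %; with real recordings the rule is more conservative, because low-
frequency drift inflates the background bins. On a *constant* field the
rejection is exactly 100 % (`static`).

## Reporting conventions

Field summaries (mean, median, modal CBF) are computed over **accepted
ROIs only**. 0 Hz is a rejection label; averaging labels into the field
mean would bias CBF downward, so the static/rejected counts are reported
separately (`include_zeros = TRUE` restores the all-ROI average for
comparison with tools that do mix them). The modal CBF is the midpoint of
the most populated histogram bin (1 Hz bins by default, lowest bin on
ties). Bland–Altman limits of agreement are the conventional
`mean difference ± 1.96 · SD` of the paired differences.

The direct-counting conversion used by observers,
`frame_rate / frames_elapsed × n_beats`, is provided as
`direct_count_cbf()` so automated and manual measurements can be compared
with `agreement()`.

## Known limitations

* Only uncompressed AVI and baseline (uncompressed) TIFF are read; lossy
  codecs corrupt the intensity oscillation and are refused rather than
  decoded approximately.
* TIFF carries no frame-rate metadata, so the recording rate must be
  supplied; an explicit rate always overrides AVI metadata, which
  high-speed cameras frequently mis-write.
* ROI tiling discards remainder pixels at the right/bottom edges to keep
  all ROIs the same size (equal-size ROIs keep magnitudes comparable).
* The simulator's CLI spec file is JSON, read with `jsonlite`.
* Beat *pattern* analysis (waveform classification, dyskinesia scoring) is
  out of scope; a normal frequency does not imply a normal pattern.
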