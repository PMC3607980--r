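# ciliafreq

Automated measurement of **ciliary beat frequency (CBF)** from high-speed
video microscopy.

Respiratory cilia beat at ~10–14 Hz to drive mucociliary clearance;
ependymal cilia in the brain beat at ~40 Hz. CBF is a standard readout in
primary ciliary dyskinesia diagnostics and in experiments on anything that
perturbs ciliary function (temperature, viscosity, toxins, infection).
Timing beats by eye from slow-motion playback is accurate but painfully
slow and biased toward regions the observer picks. `ciliafreq` measures
every region of the field automatically, and — importantly — reports
static cilia as static instead of inventing a frequency for them.

## Method

For a recording at frame rate $f_s$ with $N$ frames, each frame is tiled
with up to $40 \times 40$ equal regions of interest (ROIs). The mean pixel
intensity of ROI $r$ over time, $I_r(t)$, oscillates at the beat frequency
of the cilia inside it. Per ROI:

1. subtract the mean and take the FFT magnitude $|X_k|$,
   $k = 0 \dots N_\mathrm{fft}/2$, with
   $N_\mathrm{fft}$ = largest power of two $\le N$;
2. frequency resolution $\mathrm{FR} = f_s / N_\mathrm{fft}$; bin $k$
   represents $k \cdot \mathrm{FR}$ Hz;
3. take the dominant bin within the clinically relevant band
   (3–20 Hz respiratory, 3–60 Hz ependymal) and refine it by the
   flanking-bin centroid
   $\widehat{f} = \sum_{k-1}^{k+1} k\,\mathrm{FR}\,|X_k| \big/ \sum_{k-1}^{k+1} |X_k|$;
4. reject the ROI (CBF := 0 Hz, with a reason) unless the peak exceeds
   $3\times$ the background — the maximum of the first three non-DC
   magnitudes — and $\widehat{f}$ lies inside the band.

Field-level reports give mean/median/modal CBF over accepted ROIs, a
histogram, a heatmap (darker = higher CBF), and the rejection breakdown.
`agreement()` compares two sets of paired measurements (mean difference,
Bland–Altman limits $\bar d \pm 1.96\,s_d$, $r^2$, paired $t$), and
`direct_count_cbf()` converts an observer's frame count to Hz.

A built-in simulator (`synthetic_spec()` / `generate_video()`) renders
videos of oscillating regions with known ground truth — including
harmonic-rich sawtooth/square waveforms, pixel noise and bulb flicker — so
the whole pipeline is validated without any real recording.

## Worked example

```r
library(ciliafreq)

# a synthetic field: top half beats at 12 Hz, bottom half is static
spec <- synthetic_spec(
  frame_rate = 250, n_frames = 512, height = 100, width = 100,
  regions = list(
    synthetic_region(1, 1,  100, 50, frequency = 12, amplitude = 50, baseline = 120),
    synthetic_region(1, 51, 100, 50, frequency = 0,  amplitude = 0,  baseline = 120)),
  noise_sd = 2, seed = 42)
video <- generate_video(spec)
path <- file.path(tempdir(), "cilia.avi")
write_video(video$stack, path, format = "avi")

stack <- read_video(path)                       # frame rate from AVI header
map   <- compute_cbf(extract_traces(stack, make_grid(100, 100, 10, 10)))
map
#> <cbf_map> 100 ROIs: 52 accepted, 48 rejected; FR = 0.4883 Hz, band [3, 20] Hz
#>   accepted CBF: mean 12.04 Hz, range [7.38, 13.79] Hz
summarize_cbf(map)
#> <cbf_report>
#>   mean 12.04 Hz, median 12.10 Hz, modal 12.50 Hz, sd 0.70 Hz
#>   ROIs: 100 total = 52 accepted + 0 static + 48 below SNR + 0 out of band
```

The 50 beating ROIs are recovered at 12 Hz to within one frequency bin
(FR ≈ 0.49 Hz); the noisy static half is rejected by the 3× background
rule (with zero noise it would be labelled `static` outright). Two ROIs of
pure noise slip through — the expected false-accept rate of the 3× rule on
white noise is ~5 %.

Comparing the bundled ependymal validation table (automated vs. observer
direct counting, 5 minutes after pneumolysin exposure):

```r
d <- ependymal_cbf_table()
five <- d[d$time_min == 5, ]
agreement(five$ciliafa_hz, five$direct_obs1_hz)
#> <cbf_agreement> n = 8: mean diff -0.292 +/- 0.827 Hz, LoA [-1.91, 1.33], r^2 = 0.9734, t = -1.001 (p = 0.35)
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ciliafreq", package = "ciliafreq"))')
Rscript "$CLI" analyze recordings/*.avi --band respiratory --out results/
Rscript "$CLI" simulate --spec spec.json --out video.avi --truth truth.csv
Rscript "$CLI" agreement a.csv b.csv --out agreement.csv
```

`analyze` batch-processes any number of files with one shared
configuration (per-ROI CSV, summary CSV, histogram CSV and heatmap PNG per
file, plus a combined summary and a JSON echo of the resolved
configuration). Exit status 2 flags a partially failed batch.

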