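Package: ciliafreq
Title: Automated Ciliary Beat Frequency Measurement from High-Speed Video
Version: 0.1.0
Authors@R: person("ciliafreq", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Measures ciliary beat frequency (CBF) from high-speed video
    microscopy recordings. Frames are partitioned into a rectangular grid of
    regions of interest (up to 40 x 40); the mean pixel intensity of each
    region is extracted over time and converted to a magnitude spectrum by
    fast Fourier transformation. The dominant spectral peak is refined by
    flanking-peak averaging and screened by signal-to-background and
    frequency-band noise-rejection rules; rejected or static regions are
    reported as 0 Hz. Includes readers and writers for uncompressed AVI and
    multi-page TIFF stacks, a synthetic ciliary-video simulator with known
    ground truth for validation, field-level summary reports (mean, median,
    modal CBF, histogram, heatmap), direct-counting conversion, Bland-Altman
    method-agreement statistics, and a batch command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
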