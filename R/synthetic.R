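# Synthetic ciliary videos with known ground truth.
#
# Real validation recordings of beating cilia are large and not shippable,
# so the package carries a simulator instead: rectangular regions oscillate
# with a chosen waveform, frequency, amplitude and phase on top of a
# baseline, optionally degraded by per-pixel Gaussian noise and a global
# illumination flicker (an unstable microscope bulb shows up as exactly
# this kind of field-wide modulation inside the CBF range). The generator
# is the ground-truth oracle for every pipeline test.

#' Describe one oscillating region of a synthetic video
#'
#' @param x,y 1-based column/row of the region's top-left pixel.
#' @param width,height region extent in pixels.
#' @param waveform `"sine"`, `"sawtooth"` or `"square"`; the non-sinusoidal
#'   shapes carry harmonics and exercise the dominant-peak logic the way
#'   real, non-sinusoidal ciliary intensity traces do.
#' @param frequency oscillation frequency in Hz (must stay below Nyquist).
#' @param amplitude peak intensity excursion.
#' @param phase phase offset in radians.
#' @param baseline constant intensity added inside the region.
#' @return A list describing the region, for [synthetic_spec()].
#' @export
synthetic_region <- function(x, y, width, height,
                             waveform = c("sine", "sawtooth", "square"),
                             frequency = 12, amplitude = 50, phase = 0,
                             baseline = 120) {
  waveform <- match.arg(waveform)
  stopifnot(x >= 1, y >= 1, width >= 1, height >= 1,
            frequency >= 0, amplitude >= 0, baseline >= 0)
  list(x = as.integer(x), y = as.integer(y),
       width = as.integer(width), height = as.integer(height),
       waveform = waveform, frequency = frequency, amplitude = amplitude,
       phase = phase, baseline = baseline)
}

#' Specification of a synthetic ciliary video
#'
#' @param frame_rate acquisition rate in Hz (default 250, a typical
#'   high-speed setting for respiratory cilia).
#' @param n_frames number of frames (default 512).
#' @param height,width frame extent in pixels.
#' @param regions list of [synthetic_region()] descriptions; pixels outside
#'   every region are 0 (before noise).
#' @param noise_sd standard deviation of i.i.d. per-pixel Gaussian noise in
#'   intensity units (0 = noiseless).
#' @param flicker optional `c(frequency, amplitude)`: a global sinusoidal
#'   illumination modulation added to every pixel.
#' @param seed integer RNG seed; identical specs give identical videos.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(frame_rate = 250, n_frames = 512,
                           height = 100, width = 100,
                           regions = list(), noise_sd = 0,
                           flicker = NULL, seed = 1L) {
  stopifnot(frame_rate > 0, n_frames >= 2, height >= 1, width >= 1,
            noise_sd >= 0)
  for (rg in regions) {
    if (rg$frequency >= frame_rate / 2) {
      stop(sprintf(
        "region frequency %g Hz violates the Nyquist limit (%g Hz at %g fps)",
        rg$frequency, frame_rate / 2, frame_rate), call. = FALSE)
    }
    if (rg$y + rg$height - 1L > height || rg$x + rg$width - 1L > width) {
      stop("synthetic region exceeds frame bounds", call. = FALSE)
    }
  }
  if (!is.null(flicker)) {
    stopifnot(length(flicker) == 2L, flicker[1L] > 0, flicker[2L] >= 0)
    if (flicker[1L] >= frame_rate / 2) {
      stop("flicker frequency violates the Nyquist limit", call. = FALSE)
    }
  }
  structure(
    list(frame_rate = frame_rate, n_frames = as.integer(n_frames),
         height = as.integer(height), width = as.integer(width),
         regions = regions, noise_sd = noise_sd, flicker = flicker,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

.waveform_fun <- function(name) {
  switch(name,
    sine = sin,
    sawtooth = function(t) 2 * ((t / (2 * pi)) %% 1) - 1,
    square = function(t) ifelse(sin(t) >= 0, 1, -1),
    stop("unknown waveform: ", name, call. = FALSE)
  )
}

#' Generate a synthetic ciliary video with ground truth
#'
#' Renders the spec into a float [frame_stack()] plus a per-pixel
#' ground-truth frequency map (0 where no region oscillates). The float
#' stack is exact and used directly in oracle tests; [write_video()]
#' quantizes it to 8 bits for container round-trip tests.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `stack` (a [frame_stack()]), `truth` (height x width
#'   matrix of frequencies in Hz) and `spec`.
#' @examples
#' out <- generate_video(synthetic_spec(n_frames = 64, height = 10,
#'   width = 10, regions = list(synthetic_region(1, 1, 10, 5, frequency = 9))))
#' out$truth[1, 1]
#' @export
generate_video <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nf <- spec$n_frames; h <- spec$height; w <- spec$width
  t_s <- (seq_len(nf) - 1L) / spec$frame_rate
  frames <- array(0, c(nf, h, w))
  truth <- matrix(0, h, w)
  for (rg in spec$regions) {
    fun <- .waveform_fun(rg$waveform)
    sig <- rg$baseline + rg$amplitude * fun(2 * pi * rg$frequency * t_s +
                                              rg$phase)
    rows <- rg$y:(rg$y + rg$height - 1L)
    cols <- rg$x:(rg$x + rg$width - 1L)
    frames[, rows, cols] <- frames[, rows, cols] +
      array(sig, c(nf, length(rows), length(cols)))
    if (rg$frequency > 0 && rg$amplitude > 0) truth[rows, cols] <- rg$frequency
  }
  if (!is.null(spec$flicker) && spec$flicker[2L] > 0) {
    fl <- spec$flicker[2L] * (1 + sin(2 * pi * spec$flicker[1L] * t_s)) / 2
    frames <- frames + array(fl, c(nf, h, w))
  }
  if (spec$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(spec$seed)
    frames <- frames + array(stats::rnorm(nf * h * w, sd = spec$noise_sd),
                             c(nf, h, w))
  }
  frames <- pmax(frames, 0)   # intensities are physical light levels
  list(stack = frame_stack(frames, spec$frame_rate,
                           source_path = "<synthetic>"),
       truth = truth, spec = spec)
}

#' Write a synthetic (or any) frame stack to a lossless video file
#'
#' Thin alias of [write_video()], kept so simulator scripts read naturally.
#'
#' @inheritParams write_video
#' @return `path`, invisibly.
#' @export
write_synthetic_video <- function(stack, path, format = c("avi", "tiff"),
                                  bits = 8L) {
  write_video(stack, path, format = format, bits = bits)
}

#' Read a synthetic-video spec from a JSON file
#'
#' Schema: top-level fields `frame_rate`, `n_frames`, `height`, `width`,
#' `noise_sd`, `seed`, optional `flicker` (`{"frequency": .., "amplitude":
#' ..}`), and `regions`, a list of objects with the fields of
#' [synthetic_region()].
#'
#' @param path JSON file path.
#' @return A [synthetic_spec()].
#' @export
read_synthetic_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  regions <- lapply(j$regions %||% list(), function(rg) {
    do.call(synthetic_region, rg)
  })
  flicker <- if (!is.null(j$flicker)) {
    c(j$flicker$frequency, j$flicker$amplitude)
  }
  synthetic_spec(
    frame_rate = j$frame_rate %||% 250,
    n_frames = j$n_frames %||% 512,
    height = j$height %||% 100, width = j$width %||% 100,
    regions = regions, noise_sd = j$noise_sd %||% 0,
    flicker = flicker, seed = j$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
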