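# Minimal lossless video containers.
#
# High-speed microscopy recordings arrive as uncompressed AVI (RIFF/DIB) or
# multi-page baseline TIFF. Both are simple enough to read and write directly
# with readBin/writeBin, which keeps the package dependency-free and makes
# the round trip bit-exact -- a hard requirement, since lossy codecs corrupt
# the intensity oscillations that carry the ciliary beat signal.

## ---- little-endian raw builders -------------------------------------------

.u32 <- function(x) {
  # uint32 little-endian; values >= 2^31 go through the signed bit pattern
  x <- as.numeric(x)
  x <- ifelse(x >= 2^31, x - 2^32, x)
  writeBin(as.integer(x), raw(), size = 4L, endian = "little")
}
.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.fcc <- function(s) charToRaw(s)

.chunk <- function(id, data) {
  out <- c(.fcc(id), .u32(length(data)), data)
  if (length(data) %% 2L) out <- c(out, as.raw(0L))  # RIFF word alignment
  out
}
.list_chunk <- function(type, data) .chunk("LIST", c(.fcc(type), data))

## ---- little/big-endian raw readers ----------------------------------------

.rd_u32 <- function(raw, off, endian = "little") {
  v <- readBin(raw[off:(off + 3L)], "integer", size = 4L, endian = endian)
  if (v < 0) v + 2^32 else as.numeric(v)
}
.rd_u16 <- function(raw, off, endian = "little") {
  readBin(raw[off:(off + 1L)], "integer", size = 2L, signed = FALSE,
          endian = endian)
}
.rd_fcc <- function(raw, off) rawToChar(raw[off:(off + 3L)])

## ---- AVI writer ------------------------------------------------------------

.fps_rational <- function(fps) {
  if (abs(fps - round(fps)) < 1e-9) c(scale = 1, rate = round(fps))
  else c(scale = 1000, rate = round(fps * 1000))
}

# frames: integer array (frame, row, col) in 0..255, or (frame, row, col, 3)
# for 24-bit RGB. Rows are stored bottom-up with 4-byte alignment (DIB).
.encode_dib_frame <- function(m, stride, rgb = FALSE) {
  h <- nrow(m)
  if (!rgb) {
    buf <- matrix(as.raw(0L), nrow = stride, ncol = h)
    buf[seq_len(ncol(m)), ] <- as.raw(t(m[h:1, , drop = FALSE]))
    as.vector(buf)
  } else {
    # m is (row, col, 3); interleave as B,G,R per pixel
    w <- dim(m)[2L]
    px <- array(0L, c(3L, w, h))
    px[1L, , ] <- t(m[h:1, , 3L])
    px[2L, , ] <- t(m[h:1, , 2L])
    px[3L, , ] <- t(m[h:1, , 1L])
    buf <- matrix(as.raw(0L), nrow = stride, ncol = h)
    buf[seq_len(3L * w), ] <- as.raw(px)
    as.vector(buf)
  }
}

#' Write frames as an uncompressed AVI file
#'
#' Encodes an integer frame array as a single-stream RIFF AVI with raw DIB
#' frames (`'DIB '` handler, no compression) and a grayscale palette for
#' 8-bit input, so that [read_video()] recovers every pixel value exactly.
#'
#' @param frames integer array `(frame, row, column)` with values in 0..255,
#'   or `(frame, row, column, 3)` for 24-bit RGB.
#' @param path output file path.
#' @param frame_rate frames per second; non-integer rates are stored as a
#'   rational with millisecond precision.
#' @return `path`, invisibly.
#' @export
write_avi <- function(frames, path, frame_rate) {
  stopifnot(is.array(frames), length(dim(frames)) %in% c(3L, 4L))
  d <- dim(frames)
  rgb <- length(d) == 4L
  if (rgb && d[4L] != 3L) stop("RGB frames need exactly 3 channels",
                               call. = FALSE)
  if (min(frames) < 0 || max(frames) > 255) {
    stop("AVI output requires integer intensities in 0..255", call. = FALSE)
  }
  frames <- round(frames)
  storage.mode(frames) <- "integer"
  nf <- d[1L]; h <- d[2L]; w <- d[3L]
  bpp <- if (rgb) 24L else 8L
  stride <- ((w * (bpp %/% 8L) + 3L) %/% 4L) * 4L
  frame_bytes <- stride * h
  rat <- .fps_rational(frame_rate)

  avih <- c(
    .u32(round(1e6 / frame_rate)),       # dwMicroSecPerFrame
    .u32(frame_bytes * ceiling(frame_rate)),
    .u32(0), .u32(0),                    # padding granularity, flags
    .u32(nf), .u32(0), .u32(1),          # total frames, initial, streams
    .u32(frame_bytes), .u32(w), .u32(h),
    .u32(0), .u32(0), .u32(0), .u32(0)
  )
  strh <- c(
    .fcc("vids"), .fcc("DIB "),
    .u32(0), .u32(0), .u32(0),           # flags, priority/lang, initial
    .u32(rat[["scale"]]), .u32(rat[["rate"]]),
    .u32(0), .u32(nf), .u32(frame_bytes),
    .u32(2^32 - 1),                      # quality = -1
    .u32(0),                             # sample size
    .u16(0), .u16(0), .u16(w), .u16(h)   # rcFrame
  )
  strf <- c(
    .u32(40), .u32(w), .u32(h), .u16(1), .u16(bpp),
    .u32(0),                             # BI_RGB, uncompressed
    .u32(frame_bytes), .u32(0), .u32(0),
    .u32(if (rgb) 0 else 256), .u32(0)
  )
  if (!rgb) {
    pal <- as.raw(rbind(0:255, 0:255, 0:255, rep(0L, 256)))
    strf <- c(strf, pal)
  }
  hdrl <- .list_chunk("hdrl", c(
    .chunk("avih", avih),
    .list_chunk("strl", c(.chunk("strh", strh), .chunk("strf", strf)))
  ))
  movi_frames <- vector("list", nf)
  for (t in seq_len(nf)) {
    m <- if (rgb) frames[t, , , , drop = TRUE] else frames[t, , , drop = TRUE]
    if (!rgb && h == 1L) m <- matrix(m, nrow = 1L)
    movi_frames[[t]] <- .chunk("00db", .encode_dib_frame(m, stride, rgb))
  }
  movi <- .list_chunk("movi", do.call(c, movi_frames))
  body <- c(.fcc("AVI "), hdrl, movi)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(.fcc("RIFF"), .u32(length(body)), body), con)
  invisible(path)
}

## ---- AVI reader ------------------------------------------------------------

.read_avi <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 12L || .rd_fcc(raw, 1L) != "RIFF" ||
      .rd_fcc(raw, 9L) != "AVI ") {
    stop("not a RIFF/AVI file: ", path, call. = FALSE)
  }
  env <- new.env(parent = emptyenv())
  env$frames <- list()
  env$n_vids <- 0L

  walk <- function(off, end) {
    while (off + 8L <= end) {
      id <- .rd_fcc(raw, off)
      size <- .rd_u32(raw, off + 4L)
      data_off <- off + 8L
      if (id == "LIST" || id == "RIFF") {
        walk(data_off + 4L, data_off + size)
      } else if (id == "avih") {
        env$width <- .rd_u32(raw, data_off + 32L)
        env$height <- .rd_u32(raw, data_off + 36L)
      } else if (id == "strh") {
        if (.rd_fcc(raw, data_off) == "vids" && is.null(env$scale)) {
          env$scale <- .rd_u32(raw, data_off + 20L)
          env$rate <- .rd_u32(raw, data_off + 24L)
          env$want_strf <- TRUE
        }
      } else if (id == "strf" && isTRUE(env$want_strf)) {
        env$bpp <- .rd_u16(raw, data_off + 14L)
        env$compression <- .rd_u32(raw, data_off + 16L)
        clr_used <- .rd_u32(raw, data_off + 32L)
        if (env$bpp == 8L) {
          npal <- if (clr_used > 0) clr_used else 256
          pal_off <- data_off + 40L
          pal <- matrix(as.integer(raw[pal_off:(pal_off + npal * 4L - 1L)]),
                        nrow = 4L)
          env$palette <- colMeans(pal[1:3, , drop = FALSE])  # b,g,r equal gray
        }
        env$want_strf <- FALSE
      } else if (grepl("^..(db|dc)$", id)) {
        env$frames[[length(env$frames) + 1L]] <- raw[data_off:(data_off + size - 1L)]
      }
      off <- data_off + size + (size %% 2L)  # chunks are word-aligned
    }
  }
  walk(13L, length(raw))

  if (is.null(env$width) || is.null(env$bpp)) {
    stop("corrupt AVI (missing headers): ", path, call. = FALSE)
  }
  if (env$compression != 0) {
    stop("compressed AVI streams are not supported (found biCompression = ",
         env$compression, "); re-export the recording uncompressed: ", path,
         call. = FALSE)
  }
  if (!env$bpp %in% c(8L, 24L)) {
    stop("unsupported AVI bit depth: ", env$bpp, call. = FALSE)
  }
  nf <- length(env$frames)
  if (nf == 0L) stop("corrupt AVI (no frame data): ", path, call. = FALSE)
  w <- as.integer(env$width); h <- as.integer(env$height)
  stride <- ((w * (env$bpp %/% 8L) + 3L) %/% 4L) * 4L
  rgb <- env$bpp == 24L
  out <- if (rgb) array(0, c(nf, h, w, 3L)) else array(0, c(nf, h, w))
  for (t in seq_len(nf)) {
    fr <- env$frames[[t]]
    if (length(fr) < stride * h) {
      stop("corrupt AVI (truncated frame ", t, "): ", path, call. = FALSE)
    }
    buf <- matrix(as.integer(fr[seq_len(stride * h)]), nrow = stride)
    if (!rgb) {
      m <- t(buf[seq_len(w), , drop = FALSE])[h:1, , drop = FALSE]
      if (!is.null(env$palette)) m[] <- env$palette[m + 1L]
      out[t, , ] <- m
    } else {
      px <- array(buf[seq_len(3L * w), , drop = FALSE], c(3L, w, h))
      out[t, , , 3L] <- t(px[1L, , ])[h:1, , drop = FALSE]
      out[t, , , 2L] <- t(px[2L, , ])[h:1, , drop = FALSE]
      out[t, , , 1L] <- t(px[3L, , ])[h:1, , drop = FALSE]
    }
  }
  fps <- if (!is.null(env$scale) && env$scale > 0) env$rate / env$scale else NA_real_
  list(frames = out, frame_rate = fps)
}

## ---- TIFF writer -----------------------------------------------------------

#' Write frames as an uncompressed multi-page TIFF
#'
#' Baseline little-endian TIFF, one page per frame, one strip per page,
#' photometric BlackIsZero (or RGB for 4-D input). Values round-trip exactly
#' through [read_video()].
#'
#' @param frames integer array `(frame, row, column)` or
#'   `(frame, row, column, 3)` for RGB; values in `0 .. 2^bits - 1`.
#' @param path output file path.
#' @param bits bits per sample, 8 or 16 (RGB supports 8 only).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(frames, path, bits = 8L) {
  stopifnot(is.array(frames), length(dim(frames)) %in% c(3L, 4L),
            bits %in% c(8L, 16L))
  d <- dim(frames)
  rgb <- length(d) == 4L
  if (rgb && bits != 8L) stop("RGB TIFF output supports 8-bit only",
                              call. = FALSE)
  if (min(frames) < 0 || max(frames) > 2^bits - 1) {
    stop("TIFF output requires intensities in 0..", 2^bits - 1, call. = FALSE)
  }
  frames <- round(frames)
  storage.mode(frames) <- "integer"
  nf <- d[1L]; h <- d[2L]; w <- d[3L]
  spp <- if (rgb) 3L else 1L
  bytes_per_page <- h * w * spp * (bits %/% 8L)

  entry <- function(tag, type, count, value) {
    # type 3 = SHORT, 4 = LONG; value fits in the 4-byte field
    val <- if (type == 3L) c(.u16(value), .u16(0)) else .u32(value)
    c(.u16(tag), .u16(type), .u32(count), val)
  }
  # RGB BitsPerSample needs 3 SHORTs -> stored out-of-line after the IFDs
  n_entries <- if (rgb) 10L else 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  data_start <- 8L
  ifd_start <- data_start + nf * bytes_per_page
  extra_start <- ifd_start + nf * ifd_size

  pages <- vector("list", nf)
  ifds <- vector("list", nf)
  for (t in seq_len(nf)) {
    m <- if (rgb) frames[t, , , , drop = TRUE] else frames[t, , , drop = TRUE]
    if (!rgb && h == 1L) m <- matrix(m, nrow = 1L)
    if (!rgb) {
      vals <- as.vector(t(m))                       # row-major, top-down
    } else {
      px <- array(0L, c(3L, w, h))
      for (ch in 1:3) px[ch, , ] <- t(m[, , ch])
      vals <- as.vector(px)                         # interleaved RGB
    }
    pages[[t]] <- if (bits == 8L) as.raw(vals) else
      writeBin(as.integer(vals), raw(), size = 2L, endian = "little")
    off <- data_start + (t - 1L) * bytes_per_page
    e <- c(
      entry(256L, 4L, 1L, w),
      entry(257L, 4L, 1L, h),
      if (rgb) c(.u16(258L), .u16(3L), .u32(3L), .u32(extra_start))
      else entry(258L, 3L, 1L, bits),
      entry(259L, 3L, 1L, 1L),                      # no compression
      entry(262L, 3L, 1L, if (rgb) 2L else 1L),     # photometric
      entry(273L, 4L, 1L, off),
      entry(277L, 3L, 1L, spp),
      entry(278L, 4L, 1L, h),
      entry(279L, 4L, 1L, bytes_per_page),
      entry(339L, 3L, 1L, 1L)                       # unsigned integer data
    )
    next_ifd <- if (t < nf) ifd_start + t * ifd_size else 0L
    ifds[[t]] <- c(.u16(n_entries), e, .u32(next_ifd))
  }
  extra <- if (rgb) c(.u16(8L), .u16(8L), .u16(8L)) else raw(0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), .u16(42L), .u32(ifd_start),
             do.call(c, pages), do.call(c, ifds), extra), con)
  invisible(path)
}

## ---- TIFF reader -----------------------------------------------------------

.tiff_read_values <- function(raw, type, count, field_off, endian) {
  sz <- c(`1` = 1L, `3` = 2L, `4` = 4L)[[as.character(type)]]
  total <- sz * count
  off <- if (total <= 4L) field_off else .rd_u32(raw, field_off, endian) + 1L
  vapply(seq_len(count), function(i) {
    o <- off + (i - 1L) * sz
    switch(as.character(type),
           `1` = as.numeric(raw[o]),
           `3` = as.numeric(.rd_u16(raw, o, endian)),
           `4` = .rd_u32(raw, o, endian))
  }, numeric(1))
}

.read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  magic <- rawToChar(raw[1:2])
  endian <- switch(magic, II = "little", MM = "big",
                   stop("not a TIFF file: ", path, call. = FALSE))
  if (.rd_u16(raw, 3L, endian) != 42L) {
    stop("not a TIFF file: ", path, call. = FALSE)
  }
  ifd_off <- .rd_u32(raw, 5L, endian) + 1L
  pages <- list()
  while (ifd_off > 1L) {
    n <- .rd_u16(raw, ifd_off, endian)
    tags <- list()
    for (i in seq_len(n)) {
      eo <- ifd_off + 2L + (i - 1L) * 12L
      tag <- .rd_u16(raw, eo, endian)
      type <- .rd_u16(raw, eo + 2L, endian)
      count <- .rd_u32(raw, eo + 4L, endian)
      if (type %in% c(1L, 3L, 4L)) {
        tags[[as.character(tag)]] <-
          .tiff_read_values(raw, type, count, eo + 8L, endian)
      }
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    w <- g(256); h <- g(257)
    if (is.null(w) || is.null(h)) stop("corrupt TIFF page: ", path,
                                       call. = FALSE)
    comp <- g(259, 1)
    if (comp != 1) {
      stop("compressed TIFF (compression = ", comp,
           ") is not supported; save uncompressed: ", path, call. = FALSE)
    }
    bits <- g(258, 1)[1L]
    if (!bits %in% c(8, 16)) stop("unsupported TIFF bit depth: ", bits,
                                  call. = FALSE)
    spp <- g(277, 1)
    offsets <- g(273); counts <- g(279)
    if (is.null(offsets) || is.null(counts)) {
      stop("corrupt TIFF page (no strip data): ", path, call. = FALSE)
    }
    buf <- do.call(c, lapply(seq_along(offsets), function(i) {
      raw[(offsets[i] + 1L):(offsets[i] + counts[i])]
    }))
    vals <- if (bits == 8) as.numeric(buf) else {
      v <- readBin(buf, "integer", n = length(buf) %/% 2L, size = 2L,
                   signed = FALSE, endian = endian)
      as.numeric(v)
    }
    if (spp == 1) {
      pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w,
                                            byrow = TRUE)
    } else if (spp == 3) {
      px <- array(vals, c(3L, w, h))
      page <- array(0, c(h, w, 3L))
      for (ch in 1:3) page[, , ch] <- t(px[ch, , ])
      pages[[length(pages) + 1L]] <- page
    } else {
      stop("unsupported TIFF samples per pixel: ", spp, call. = FALSE)
    }
    ifd_off <- .rd_u32(raw, ifd_off + 2L + n * 12L, endian) + 1L
  }
  if (!length(pages)) stop("TIFF contains no pages: ", path, call. = FALSE)
  rgb <- length(dim(pages[[1L]])) == 3L
  d <- dim(pages[[1L]])
  out <- if (rgb) array(0, c(length(pages), d[1L], d[2L], 3L)) else
    array(0, c(length(pages), d[1L], d[2L]))
  for (t in seq_along(pages)) {
    if (!identical(dim(pages[[t]]), d)) {
      stop("TIFF pages have inconsistent dimensions: ", path, call. = FALSE)
    }
    if (rgb) out[t, , , ] <- pages[[t]] else out[t, , ] <- pages[[t]]
  }
  list(frames = out, frame_rate = NA_real_)
}

## ---- user-facing readers / writers ----------------------------------------

#' Read a high-speed video recording into a frame stack
#'
#' Reads an uncompressed AVI or multi-page TIFF stack, converts RGB input to
#' grayscale, and attaches the acquisition frame rate. AVI carries a frame
#' rate in its stream header; TIFF does not, so `frame_rate_override` is
#' mandatory for TIFF input. An explicit override always wins over container
#' metadata, because frame-rate metadata written by high-speed cameras is
#' frequently wrong.
#'
#' @param path path to an `.avi` or `.tif`/`.tiff` file.
#' @param frame_rate_override frames per second; required when the container
#'   has no (or an untrusted) frame rate.
#' @param gray_method RGB-to-grayscale conversion, see [rgb_to_gray()].
#' @return A [frame_stack()].
#' @examples
#' fs <- generate_video(synthetic_spec(n_frames = 16, height = 8, width = 8,
#'   regions = list(synthetic_region(1, 1, 8, 8, frequency = 10))))$stack
#' f <- tempfile(fileext = ".avi")
#' write_video(fs, f, format = "avi")
#' read_video(f)
#' @export
read_video <- function(path, frame_rate_override = NULL,
                       gray_method = c("mean", "luma")) {
  gray_method <- match.arg(gray_method)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  magic <- readBin(path, "raw", n = 4L)
  kind <- if (length(magic) >= 4L && rawToChar(magic) == "RIFF") "avi"
  else if (length(magic) >= 2L && rawToChar(magic[1:2]) %in% c("II", "MM"))
    "tiff"
  else stop("unrecognized video container (expected uncompressed AVI or ",
            "TIFF): ", path, call. = FALSE)
  parsed <- if (kind == "avi") .read_avi(path) else .read_tiff(path)
  fps <- if (!is.null(frame_rate_override)) frame_rate_override
  else parsed$frame_rate
  if (is.null(fps) || is.na(fps)) {
    stop("no frame rate in ", toupper(kind), " metadata; supply ",
         "`frame_rate_override` (the recording rate in fps)", call. = FALSE)
  }
  frames <- parsed$frames
  if (length(dim(frames)) == 4L) frames <- rgb_to_gray(frames, gray_method)
  frame_stack(frames, fps, source_path = path)
}

#' Write a frame stack to a lossless video file
#'
#' Quantizes intensities to the container bit depth (round-half-even, clipped
#' to the representable range) and writes an uncompressed AVI or multi-page
#' TIFF. For stacks already holding 8-bit integer values the round trip
#' through [read_video()] is exact.
#'
#' @param stack a [frame_stack()].
#' @param path output path.
#' @param format `"avi"` or `"tiff"`.
#' @param bits bits per sample (8 for AVI; 8 or 16 for TIFF).
#' @return `path`, invisibly.
#' @export
write_video <- function(stack, path, format = c("avi", "tiff"), bits = 8L) {
  stopifnot(inherits(stack, "frame_stack"))
  format <- match.arg(format)
  if (format == "avi" && bits != 8L) {
    stop("AVI output is 8-bit only", call. = FALSE)
  }
  q <- pmin(pmax(round(stack$frames), 0), 2^bits - 1)
  if (format == "avi") write_avi(q, path, stack$frame_rate)
  else write_tiff(q, path, bits = bits)
  invisible(path)
}
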