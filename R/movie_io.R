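#' Construct acquisition metadata
#'
#' @param width,height Frame size in pixels.
#' @param nFrames Number of frames.
#' @param frameRate Frames per second (Hz).
#' @param pixelSize Pixel side length in micrometres.
#' @param bitDepth Unsigned integer bit depth, 8 or 16.
#' @param byteOrder Byte order of raw streams, `"little"` or `"big"`.
#' @return An [AcquisitionMeta-class] object.
#' @examples
#' acquisitionMeta(512, 512, 100)
#' @export
acquisitionMeta <- function(width, height, nFrames, frameRate = 28.77,
                            pixelSize = 0.4, bitDepth = 16L,
                            byteOrder = c("little", "big")) {
  new("AcquisitionMeta",
      width = as.integer(width), height = as.integer(height),
      nFrames = as.integer(nFrames), frameRate = as.numeric(frameRate),
      pixelSize = as.numeric(pixelSize), bitDepth = as.integer(bitDepth),
      byteOrder = match.arg(byteOrder))
}

#' Construct a movie stack
#'
#' @param data 3D array of non-negative integer intensities, indexed
#'   `(frame, row, column)`.
#' @param meta An [AcquisitionMeta-class]; if missing, one is derived from
#'   `dim(data)` with the remaining arguments.
#' @param ... Passed to [acquisitionMeta()] when `meta` is missing.
#' @return A [MovieStack-class].
#' @examples
#' movieStack(array(100L, c(5, 4, 4)))
#' @export
movieStack <- function(data, meta = NULL, ...) {
  d <- dim(data)
  if (is.null(meta))
    meta <- acquisitionMeta(width = d[3L], height = d[2L], nFrames = d[1L], ...)
  new("MovieStack", data = data, meta = meta)
}

#' Read and write the plain-text metadata descriptor
#'
#' A raw movie is a headerless stream; its geometry lives in a sidecar
#' key-value text file with keys `width`, `height`, `n_frames`,
#' `frame_rate_hz`, `pixel_size_um`, `bit_depth`, `byte_order`.
#'
#' @param path Path of the descriptor file.
#' @param meta An [AcquisitionMeta-class] (for writing).
#' @return `readAcquisitionMeta()` returns an [AcquisitionMeta-class];
#'   `writeAcquisitionMeta()` returns `path` invisibly.
#' @export
readAcquisitionMeta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[[1L]]), "")
  vals <- vapply(kv, function(x) trimws(paste(x[-1L], collapse = ":")), "")
  need <- c("width", "height", "n_frames")
  if (!all(need %in% keys))
    stop("metadata descriptor must define: ", paste(need, collapse = ", "))
  get <- function(key, default) if (key %in% keys) vals[match(key, keys)] else default
  acquisitionMeta(
    width = as.integer(get("width", NA)),
    height = as.integer(get("height", NA)),
    nFrames = as.integer(get("n_frames", NA)),
    frameRate = as.numeric(get("frame_rate_hz", 28.77)),
    pixelSize = as.numeric(get("pixel_size_um", 0.4)),
    bitDepth = as.integer(get("bit_depth", 16L)),
    byteOrder = get("byte_order", "little"))
}

#' @rdname readAcquisitionMeta
#' @export
writeAcquisitionMeta <- function(meta, path) {
  stopifnot(is(meta, "AcquisitionMeta"))
  writeLines(c(
    sprintf("width: %d", meta@width),
    sprintf("height: %d", meta@height),
    sprintf("n_frames: %d", meta@nFrames),
    sprintf("frame_rate_hz: %.10g", meta@frameRate),
    sprintf("pixel_size_um: %.10g", meta@pixelSize),
    sprintf("bit_depth: %d", meta@bitDepth),
    sprintf("byte_order: %s", meta@byteOrder)), path)
  invisible(path)
}

#' Read a headerless raw movie stream
#'
#' The stream holds unsigned integers of the declared bit depth, row-major
#' within each frame, frames concatenated in acquisition order, in the
#' declared byte order. The file size must equal
#' `width * height * nFrames * bitDepth/8` bytes exactly.
#'
#' @param path Path of the raw file.
#' @param meta An [AcquisitionMeta-class] describing the stream, or the
#'   path of its sidecar descriptor (see [readAcquisitionMeta()]).
#' @return A [MovieStack-class].
#' @seealso [writeMovie()], [readTiffMovie()]
#' @export
readRawMovie <- function(path, meta) {
  if (is.character(meta)) meta <- readAcquisitionMeta(meta)
  stopifnot(is(meta, "AcquisitionMeta"))
  if (!file.exists(path)) stop("cannot read movie file: ", path)
  bytesPer <- meta@bitDepth %/% 8L
  nVals <- as.numeric(meta@width) * meta@height * meta@nFrames
  expected <- nVals * bytesPer
  actual <- file.size(path)
  if (actual != expected)
    stop(sprintf(
      "raw file size mismatch: expected %.0f bytes (%d x %d x %d at %d bits) but found %.0f",
      expected, meta@width, meta@height, meta@nFrames, meta@bitDepth, actual))
  v <- readBin(path, what = "integer", n = nVals, size = bytesPer,
               signed = FALSE,
               endian = if (meta@byteOrder == "little") "little" else "big")
  # stream order: x fastest, then y, then t -> fill (x, y, t), rotate to (t, y, x)
  arr <- aperm(array(as.numeric(v), dim = c(meta@width, meta@height, meta@nFrames)),
               c(3L, 2L, 1L))
  new("MovieStack", data = arr, meta = meta)
}

#' Read a multi-page TIFF movie
#'
#' Pages become frames in file order. Only grayscale (single-sample) 8- or
#' 16-bit pages are supported. Frame rate and pixel size are not part of
#' baseline TIFF and are taken from the arguments.
#'
#' @param path Path of the TIFF file.
#' @param frameRate,pixelSize Acquisition metadata not stored in TIFF.
#' @param byteOrder Recorded in the metadata for later raw export.
#' @return A [MovieStack-class].
#' @seealso [writeMovie()]
#' @export
readTiffMovie <- function(path, frameRate = 28.77, pixelSize = 0.4,
                          byteOrder = "little") {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, function(p) is.matrix(p), TRUE)))
    stop("unsupported TIFF: pages with multiple samples per pixel (RGB?) found; only grayscale is supported")
  d <- dim(pages[[1L]])
  if (any(vapply(pages, function(p) !identical(dim(p), d), TRUE)))
    stop("unsupported TIFF: pages differ in size")
  bits <- attr(pages[[1L]], "bits.per.sample")
  bitDepth <- if (!is.null(bits)) as.integer(bits[[1L]])
              else if (max(vapply(pages, max, 0)) > 255) 16L else 8L
  arr <- array(0, dim = c(length(pages), d[1L], d[2L]))
  for (t in seq_along(pages)) arr[t, , ] <- pages[[t]]
  movieStack(arr, meta = acquisitionMeta(
    width = d[2L], height = d[1L], nFrames = length(pages),
    frameRate = frameRate, pixelSize = pixelSize, bitDepth = bitDepth,
    byteOrder = byteOrder))
}

#' Write a movie to disk
#'
#' `format = "raw"` writes the headerless unsigned-integer stream (plus, if
#' `writeMeta`, the sidecar descriptor at `<path>.meta`); `format = "tiff"`
#' writes a baseline multi-page grayscale TIFF. Both are lossless: the
#' matching reader reproduces the stack exactly.
#'
#' @param stack A [MovieStack-class].
#' @param path Output file path.
#' @param format `"raw"` or `"tiff"`.
#' @param writeMeta For raw output, also write the sidecar descriptor.
#' @return `path`, invisibly.
#' @seealso [readRawMovie()], [readTiffMovie()]
#' @export
writeMovie <- function(stack, path, format = c("raw", "tiff"),
                       writeMeta = TRUE) {
  stopifnot(is(stack, "MovieStack"))
  validObject(stack)
  format <- match.arg(format)
  m <- stack@meta
  if (format == "raw") {
    v <- as.integer(round(aperm(stack@data, c(3L, 2L, 1L))))
    if (m@bitDepth == 8L) {
      bytes <- as.raw(v)
    } else {
      lo <- v %% 256L
      hi <- v %/% 256L
      bytes <- if (m@byteOrder == "little") as.raw(rbind(lo, hi))
               else as.raw(rbind(hi, lo))
    }
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(bytes, con)
    if (writeMeta) writeAcquisitionMeta(m, paste0(path, ".meta"))
  } else {
    scale <- 2^m@bitDepth - 1
    pages <- lapply(seq_len(m@nFrames), function(t)
      matrix(stack@data[t, , ] / scale, m@height, m@width))
    tiff::writeTIFF(pages, path, bits.per.sample = m@bitDepth,
                    compression = "none", reduce = FALSE)
  }
  invisible(path)
}
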