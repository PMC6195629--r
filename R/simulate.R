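#' Estimate a per-pixel noise model from a recorded movie
#'
#' Computes every pixel's temporal mean and standard deviation (sample
#' convention, denominator `n - 1`). The two maps characterize the
#' background of an EM-CCD recording well enough to resynthesize
#' statistically similar noise frames.
#'
#' @param stack A [MovieStack-class] or bare 3D array with >= 2 frames.
#' @return A [NoiseModel-class] with `source = "from_movie"`.
#' @seealso [syntheticNoiseModel()], [simulateMovie()]
#' @export
estimateNoiseModel <- function(stack) {
  arr <- if (is(stack, "MovieStack")) stack@data else stack
  d <- dim(arr)
  if (d[1L] < 2L) stop("need at least 2 frames to estimate a noise model")
  M <- asFramePixelMatrix(arr)
  n <- d[1L]
  mu <- colMeans(M)
  ss <- colSums(M^2) - n * mu^2
  sdv <- sqrt(pmax(ss, 0) / (n - 1))
  new("NoiseModel",
      meanMap = matrix(mu, d[2L], d[3L]),
      stdMap = matrix(sdv, d[2L], d[3L]),
      source = "from_movie")
}

#' Synthetic cell-on-background noise model
#'
#' Generates the mean/std maps of an EM-CCD-like field of view containing
#' one smooth, bright, roughly circular cell on a dark background, so the
#' SNR benchmark needs no recorded data. The fluorescence signal map is a
#' hard disc softened by a Gaussian edge, sitting on a constant camera
#' bias `offset`; the std map is shot-noise-like,
#' `stdMap = sqrt(readNoise^2 + k * signal)`, with the shot factor `k`
#' calibrated so the coefficient of variation at the cell plateau equals
#' `noiseCv`. Dim background pixels are therefore relatively much quieter
#' than the cell (bias dominates their mean, read noise their
#' fluctuation), reproducing the characteristic intensity-noise structure
#' of EM-CCD fluorescence frames. The returned mask (pixels whose mean
#' exceeds the grand mean) is by construction the same rule
#' [computeInclusionMask()] applies to a movie sampled from the model.
#'
#' @param height,width Field size in pixels.
#' @param cellCenter `(row, col)` of the cell centre; default the field
#'   centre.
#' @param cellRadius Disc radius in pixels; default `0.28 * min(height,
#'   width)`, putting ~25% of the field inside the cell.
#' @param edgeSigma Gaussian softening of the disc edge, px.
#' @param bgMean,cellMean Background and cell fluorescence signal levels
#'   in camera counts *above* the bias; must satisfy
#'   `cellMean > bgMean > 0`.
#' @param offset Camera bias added to every pixel's mean, counts.
#' @param readNoise Signal-independent noise floor, counts (SD).
#' @param noiseCv Coefficient of variation (SD / mean) at the cell
#'   plateau; fixes the shot-noise factor.
#' @return A list with `noise` (a [NoiseModel-class], `source =
#'   "synthetic"`) and `mask` (logical matrix).
#' @export
syntheticNoiseModel <- function(height = 64L, width = 64L, cellCenter = NULL,
                                cellRadius = NULL, edgeSigma = 2,
                                bgMean = 10, cellMean = 600, offset = 200,
                                readNoise = 6, noiseCv = 0.1) {
  if (!(cellMean > bgMean && bgMean > 0))
    stop("need cellMean > bgMean > 0")
  if (is.null(cellCenter)) cellCenter <- c((height + 1) / 2, (width + 1) / 2)
  if (is.null(cellRadius)) cellRadius <- 0.28 * min(height, width)
  if (cellRadius <= 0 || cellRadius > max(height, width))
    stop("degenerate cell geometry: radius must be in (0, max(height, width)]")
  if (noiseCv < 0) stop("'noiseCv' must be >= 0")
  stdCell <- noiseCv * (offset + cellMean)
  if (stdCell^2 < readNoise^2)
    stop("'readNoise' alone exceeds the requested cell-level noise")
  shotFactor <- (stdCell^2 - readNoise^2) / cellMean
  rr <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  disc <- (rr - cellCenter[1L])^2 + (cc - cellCenter[2L])^2 <= cellRadius^2
  if (!any(disc)) stop("degenerate cell geometry: disc contains no pixels")
  blob <- smooth2d(disc * 1, edgeSigma)
  signal <- bgMean + (cellMean - bgMean) * blob
  meanMap <- offset + signal
  noise <- new("NoiseModel", meanMap = meanMap,
               stdMap = sqrt(readNoise^2 + shotFactor * signal),
               source = "synthetic")
  list(noise = noise, mask = meanMap > mean(meanMap))
}

#' Normalized event waveform template
#'
#' A difference-of-exponentials transient `(1 - exp(-t/riseTau)) *
#' exp(-t/decayTau)` sampled at the frame rate, renormalized to peak
#' exactly 1 and truncated where it falls below 1% of the peak. The
#' defaults (15 ms rise, 200 ms decay) give GCaMP6f-scale single-spike
#' kinetics; the template used is recorded in every simulation's ground
#' truth so results are attributable to it.
#'
#' @param frameRate Sampling rate in Hz.
#' @param riseTau,decayTau Time constants in seconds, > 0.
#' @return An [EventTemplate-class].
#' @export
makeEventTemplate <- function(frameRate = 28.77, riseTau = 0.015,
                              decayTau = 0.2) {
  stopifnot(riseTau > 0, decayTau > 0, frameRate > 0)
  horizon <- decayTau * 12 + riseTau * 12
  t <- seq(0, horizon, by = 1 / frameRate)
  w <- (1 - exp(-t / riseTau)) * exp(-t / decayTau)
  w <- w / max(w)
  last <- max(which(w >= 0.01))
  new("EventTemplate", samples = w[seq_len(last)], frameRate = frameRate,
      riseTau = riseTau, decayTau = decayTau,
      description = sprintf(
        "difference-of-exponentials, rise %g ms / decay %g ms at %.2f Hz",
        riseTau * 1000, decayTau * 1000, frameRate))
}

#' Simulate a noisy movie with ground-truth events
#'
#' Builds a synthetic recording in six steps: (1) unit impulses are placed
#' at `nEvents` uniformly random `(frame, row, col)` positions with the
#' pixel inside the cell mask and the frame inside the usable range
#' (after the baseline warm-up and at least one template length before the
#' end, so every seeded event is detectable in principle); (2) each frame
#' is spread spatially with a 2D Gaussian (sigma 1 px), peak-normalized so
#' the event keeps amplitude 1 at its centre; (3) the stack is
#' convolved causally in time with the normalized event template (the
#' event starts at its seed frame); (4) the event signal is scaled
#' per-pixel by `snr * stdMap`, expressing amplitude as a multiple of the
#' local noise; (5) background frames are drawn independently as
#' `N(meanMap, stdMap^2)`; (6) signal and background are summed, clipped
#' at 0, rounded and clamped to the 16-bit range. Everything is a
#' deterministic function of `seed`.
#'
#' The ground truth records the seed coordinates, the usable frame range,
#' and the event rate implied by `nEvents / duration`; a message reports
#' the implied rate when it differs from the requested `eventRate` by more
#' than 10%.
#'
#' @param noise A [NoiseModel-class].
#' @param mask Logical cell mask; events are seeded only inside it.
#' @param template An [EventTemplate-class].
#' @param snr Signal-to-noise ratio (event amplitude in units of the
#'   pixel's noise standard deviation); 0 gives pure background.
#' @param nEvents Number of events.
#' @param eventRate Intended event rate (Hz), recorded for bookkeeping.
#' @param nFrames Number of frames; the default 286 makes 100 events at
#'   28.77 Hz average 0.35 events per frame (10 Hz).
#' @param frameRate Hz.
#' @param warmupFrames Frames at the start excluded from seeding (the
#'   baseline warm-up of the detector).
#' @param pixelSize Recorded in the movie metadata, um/px.
#' @param seed Integer RNG seed.
#' @return A list with `movie` (a [MovieStack-class]) and `truth` (a
#'   [GroundTruth-class]).
#' @export
simulateMovie <- function(noise, mask, template, snr, nEvents = 100L,
                          eventRate = 10, nFrames = 286L, frameRate = 28.77,
                          warmupFrames = 15L, pixelSize = 0.4, seed = 1L) {
  stopifnot(is(noise, "NoiseModel"), is(template, "EventTemplate"))
  if (!any(mask)) stop("cell mask is empty")
  if (snr < 0) stop("'snr' must be >= 0")
  dmap <- dim(noise@meanMap)
  H <- dmap[1L]; W <- dmap[2L]
  if (!identical(dim(mask), dmap))
    stop("mask and noise maps must share dimensions")
  tmplLen <- length(template@samples)
  fFirst <- warmupFrames + 1L
  fLast <- nFrames - tmplLen
  if (fLast < fFirst)
    stop(sprintf(
      "movie too short: %d frames leave no usable seeding range (warm-up %d + template %d)",
      nFrames, warmupFrames, tmplLen))
  implied <- nEvents / (nFrames / frameRate)
  if (abs(implied - eventRate) > 0.1 * eventRate)
    message(sprintf(
      "simulateMovie: implied event rate %.2f Hz (%.3f per frame) differs from the requested %g Hz",
      implied, nEvents / nFrames, eventRate))
  set.seed(as.integer(seed))
  maskIdx <- which(mask)                 # linear (row, col) indices
  pick <- maskIdx[sample.int(length(maskIdx), nEvents, replace = TRUE)]
  evRow <- ((pick - 1L) %% H) + 1L
  evCol <- ((pick - 1L) %/% H) + 1L
  evFrame <- fFirst + sample.int(fLast - fFirst + 1L, nEvents,
                                 replace = TRUE) - 1L
  # (1) seed impulses
  sig <- array(0, dim = c(nFrames, H, W))
  idx <- cbind(evFrame, evRow, evCol)
  for (i in seq_len(nEvents))            # accumulate overlapping seeds
    sig[idx[i, 1L], idx[i, 2L], idx[i, 3L]] <-
      sig[idx[i, 1L], idx[i, 2L], idx[i, 3L]] + 1
  # (2) spatial spread, only on frames that carry seeds; the kernel is
  # peak-normalized (centre weight 1) so an event's spatio-temporal peak
  # equals exactly snr * std after step (4) -- the definition of SNR
  for (t in unique(evFrame))
    sig[t, , ] <- smooth2d(sig[t, , ], 1, normalize = "peak")
  # (3) causal temporal convolution with the template, restricted to the
  # pixels that actually carry event signal after the spatial spread
  M <- asFramePixelMatrix(sig)
  sdv <- as.numeric(noise@stdMap)
  active <- which(colSums(abs(M)) > 0)
  K <- tmplLen
  Ma <- rbind(matrix(0, K - 1L, length(active)), M[, active, drop = FALSE])
  Ma <- bandConvolve(Ma, rev(template@samples), mode = "valid")
  # (4) per-pixel SNR scaling
  Ma <- Ma * (snr * matrix(sdv[active], nFrames, length(active), byrow = TRUE))
  # (5) background draws
  out <- matrix(stats::rnorm(nFrames * H * W,
                             mean = rep(as.numeric(noise@meanMap), each = nFrames),
                             sd = rep(sdv, each = nFrames)),
                nFrames, H * W)
  # (6) combine and quantize
  out[, active] <- out[, active, drop = FALSE] + Ma
  out <- round(pmax(out, 0))
  out[out > 65535] <- 65535
  movie <- movieStack(array(out, dim = c(nFrames, H, W)),
                      meta = acquisitionMeta(
                        width = W, height = H, nFrames = nFrames,
                        frameRate = frameRate, pixelSize = pixelSize,
                        bitDepth = 16L))
  truth <- new("GroundTruth",
    events = data.frame(event_id = seq_len(nEvents), frame = evFrame,
                        row = evRow, col = evCol),
    snr = as.numeric(snr), seed = as.integer(seed),
    params = list(
      nEvents = nEvents, eventRate = eventRate, impliedRate = implied,
      nFrames = nFrames, frameRate = frameRate,
      warmupFrames = warmupFrames, templateLength = tmplLen,
      usableFrames = c(fFirst, fLast), template = template@description,
      noiseSource = noise@source))
  list(movie = movie, truth = truth)
}

#' Write a simulation's ground truth to CSV
#'
#' @param truth A [GroundTruth-class].
#' @param path Output CSV path; the parameter echo goes to
#'   `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  utils::write.csv(truth@events, path, row.names = FALSE)
  manifest <- c(list(snr = truth@snr, seed = truth@seed), truth@params)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
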