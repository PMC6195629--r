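#' @import methods
NULL

#' Acquisition metadata for a time-lapse movie
#'
#' Describes the geometry and timing of a movie: frame size in pixels, frame
#' count, frame rate, physical pixel size and the integer encoding of the
#' stored intensities. The pixel size is the side length of one (square)
#' pixel in micrometres, so one pixel covers `pixelSize^2` square
#' micrometres; at the reference calibration of 0.4 um/px a pixel covers
#' 0.16 um^2.
#'
#' @slot width,height Frame dimensions in pixels.
#' @slot nFrames Number of frames.
#' @slot frameRate Acquisition rate in Hz.
#' @slot pixelSize Pixel side length in micrometres.
#' @slot bitDepth Unsigned-integer bit depth of the stored data (8 or 16).
#' @slot byteOrder `"little"` or `"big"`; byte order of raw on-disk streams.
#'
#' @seealso [acquisitionMeta()], [MovieStack-class]
#' @exportClass AcquisitionMeta
setClass("AcquisitionMeta",
  representation(
    width = "integer", height = "integer", nFrames = "integer",
    frameRate = "numeric", pixelSize = "numeric",
    bitDepth = "integer", byteOrder = "character"
  ),
  prototype(
    frameRate = 28.77, pixelSize = 0.4, bitDepth = 16L, byteOrder = "little"
  )
)

setValidity("AcquisitionMeta", function(object) {
  msg <- character()
  if (length(object@width) != 1L || object@width < 1L)
    msg <- c(msg, "'width' must be a single integer >= 1")
  if (length(object@height) != 1L || object@height < 1L)
    msg <- c(msg, "'height' must be a single integer >= 1")
  if (length(object@nFrames) != 1L || object@nFrames < 1L)
    msg <- c(msg, "'nFrames' must be a single integer >= 1")
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0)
    msg <- c(msg, "'frameRate' must be a single positive number (Hz)")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "'pixelSize' must be a single positive number (um)")
  if (!object@bitDepth %in% c(8L, 16L))
    msg <- c(msg, "'bitDepth' must be 8 or 16")
  if (!object@byteOrder %in% c("little", "big"))
    msg <- c(msg, "'byteOrder' must be \"little\" or \"big\"")
  if (length(msg)) msg else TRUE
})

#' A raw intensity time-lapse movie
#'
#' Holds the movie as a 3D numeric array indexed `(frame, row, column)`
#' together with its [AcquisitionMeta-class]. Values must be non-negative
#' integers representable at the declared bit depth. All indices in this
#' package are 1-based, R style.
#'
#' @slot data 3D array, dimensions `(nFrames, height, width)`.
#' @slot meta An [AcquisitionMeta-class] object.
#'
#' @seealso [movieStack()], [readRawMovie()], [readTiffMovie()]
#' @exportClass MovieStack
setClass("MovieStack",
  representation(data = "array", meta = "AcquisitionMeta")
)

setValidity("MovieStack", function(object) {
  d <- dim(object@data)
  m <- object@meta
  if (length(d) != 3L)
    return("'data' must be a 3D array (frame, row, column)")
  if (!identical(as.integer(d), c(m@nFrames, m@height, m@width)))
    return(sprintf(
      "data dimensions (%s) do not match meta (nFrames=%d, height=%d, width=%d)",
      paste(d, collapse = " x "), m@nFrames, m@height, m@width))
  rng <- suppressWarnings(range(object@data))   # one pass; NA if any NA
  if (anyNA(rng) || !all(is.finite(rng)))
    return("'data' contains NA or non-finite values")
  if (rng[1L] < 0)
    return("'data' contains negative values")
  vmax <- 2^m@bitDepth - 1
  if (rng[2L] > vmax)
    return(sprintf("'data' exceeds the %d-bit range [0, %d]", m@bitDepth, vmax))
  if (!isTRUE(all(object@data == trunc(object@data))))
    return("'data' must be integer-valued")
  TRUE
})

#' A dF/F0-transformed movie
#'
#' The moving-baseline relative fluorescence change computed by
#' [computeDff()]. Frames before `validFrom` have no fully defined baseline
#' window and are stored as `NA`; they are excluded from detection.
#'
#' @slot data 3D array of dF/F0 values, `(frame, row, column)`.
#' @slot validFrom 1-based index of the first frame with a complete
#'   baseline window.
#' @slot meta The movie's [AcquisitionMeta-class].
#'
#' @seealso [computeDff()], [binarizeDff()]
#' @exportClass DffStack
setClass("DffStack",
  representation(data = "array", validFrom = "integer", meta = "AcquisitionMeta")
)

setValidity("DffStack", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return("'data' must be a 3D array (frame, row, column)")
  vf <- object@validFrom
  if (length(vf) != 1L || vf < 1L || vf > d[1L])
    return("'validFrom' must be a frame index within the movie")
  valid <- object@data[vf:d[1L], , , drop = FALSE]
  if (anyNA(valid) || any(!is.finite(valid)))
    return("dF/F0 values on valid frames must be finite")
  TRUE
})

#' Detection parameters
#'
#' All tunable parameters of the detection pipeline. Defaults mirror the
#' reference acquisition conditions: a 3 px spatial / 2 frame temporal
#' Gaussian, a baseline window of frames t-15 ... t-5 (11 samples), a
#' per-frame threshold at median + 3 x IQR, 26-connected 3D grouping, and
#' removal of single-voxel ROIs.
#'
#' @slot sigmaSpatial Gaussian sigma in pixels for the row/column axes.
#' @slot sigmaTemporal Gaussian sigma in frames for the time axis.
#' @slot baselineWindow Integer pair `(far, near)`: F0 at frame t averages
#'   frames `t-far ... t-near`; must satisfy `far >= near >= 1`.
#' @slot thresholdK IQR multiplier of the per-frame threshold.
#' @slot minVoxels Minimum ROI size in voxels (hot-pixel filter).
#' @slot useMask Whether ROIs outside the inclusion mask are rejected.
#' @slot maskMode `"peak"`: membership judged by the ROI peak pixel;
#'   `"any"`: any voxel inside the mask suffices.
#' @slot connectivity 3D neighbourhood: 6, 18 or 26.
#' @slot contextFrames Frames of context appended on each side of an ROI
#'   when extracting its trace.
#' @slot baselineFrames Number of initial pre-peak trace frames averaged as
#'   the kinetics baseline.
#'
#' @seealso [filterConfig()], [detectEvents()]
#' @exportClass FilterConfig
setClass("FilterConfig",
  representation(
    sigmaSpatial = "numeric", sigmaTemporal = "numeric",
    baselineWindow = "integer", thresholdK = "numeric",
    minVoxels = "integer", useMask = "logical", maskMode = "character",
    connectivity = "integer", contextFrames = "integer",
    baselineFrames = "integer"
  ),
  prototype(
    sigmaSpatial = 3, sigmaTemporal = 2, baselineWindow = c(15L, 5L),
    thresholdK = 3, minVoxels = 2L, useMask = TRUE, maskMode = "peak",
    connectivity = 26L, contextFrames = 30L, baselineFrames = 10L
  )
)

setValidity("FilterConfig", function(object) {
  msg <- character()
  if (object@sigmaSpatial < 0 || object@sigmaTemporal < 0)
    msg <- c(msg, "Gaussian sigmas must be >= 0")
  bw <- object@baselineWindow
  if (length(bw) != 2L || bw[1L] < bw[2L] || bw[2L] < 1L)
    msg <- c(msg, "'baselineWindow' must be (far, near) with far >= near >= 1")
  if (object@thresholdK <= 0)
    msg <- c(msg, "'thresholdK' must be > 0")
  if (object@minVoxels < 1L)
    msg <- c(msg, "'minVoxels' must be >= 1")
  if (!object@connectivity %in% c(6L, 18L, 26L))
    msg <- c(msg, "'connectivity' must be 6, 18 or 26")
  if (!object@maskMode %in% c("peak", "any"))
    msg <- c(msg, "'maskMode' must be \"peak\" or \"any\"")
  if (object@contextFrames < 0L)
    msg <- c(msg, "'contextFrames' must be >= 0")
  if (object@baselineFrames < 1L)
    msg <- c(msg, "'baselineFrames' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' A 3D region of interest (one putative event)
#'
#' A maximal connected set of supra-threshold voxels in `(frame, row,
#' column)` space. The footprint may change from frame to frame; the union
#' footprint is the union of all per-frame pixel sets.
#'
#' @slot voxels Integer matrix, one row per voxel, columns
#'   `frame`, `row`, `col`.
#' @slot dffValues dF/F0 value of each voxel (same order as `voxels`).
#' @slot peak `(frame, row, col)` of the voxel with maximal dF/F0.
#' @slot peakDff dF/F0 at the peak voxel.
#' @slot centroid dF/F0-weighted centroid `(frame, row, col)`, real-valued.
#'
#' @seealso [labelComponents3d()], [nVoxels()], [unionFootprint()]
#' @exportClass Roi3D
setClass("Roi3D",
  representation(
    voxels = "matrix", dffValues = "numeric",
    peak = "integer", peakDff = "numeric", centroid = "numeric"
  )
)

setValidity("Roi3D", function(object) {
  v <- object@voxels
  if (!is.numeric(v) || ncol(v) != 3L || nrow(v) < 1L)
    return("'voxels' must be a non-empty matrix with 3 columns")
  if (length(object@dffValues) != nrow(v))
    return("'dffValues' must have one value per voxel")
  p <- object@peak
  if (length(p) != 3L ||
      !any(v[, 1L] == p[1L] & v[, 2L] == p[2L] & v[, 3L] == p[3L]))
    return("'peak' must be one of the ROI's voxels")
  TRUE
})

#' Result of running the detection pipeline
#'
#' @slot rois List of accepted [Roi3D-class] objects.
#' @slot thresholds Per-frame threshold in dF/F0 units (`NA` on frames
#'   before the baseline warm-up).
#' @slot mask Logical inclusion mask `(row, column)`, or `NULL`-like all-TRUE.
#' @slot config The [FilterConfig-class] used.
#' @slot rejected Named integer tally of ROIs dropped per rejection reason.
#' @slot validFrom First valid frame of the underlying [DffStack-class].
#' @slot provenance List of run information (input identifier, package
#'   version).
#'
#' @seealso [detectEvents()], [eventRecords()]
#' @exportClass DetectionResult
setClass("DetectionResult",
  representation(
    rois = "list", thresholds = "numeric", mask = "matrix",
    config = "FilterConfig", rejected = "integer", validFrom = "integer",
    provenance = "list"
  )
)

#' An extracted event trace
#'
#' Mean dF/F0 over a fixed pixel footprint, on a frame window spanning the
#' ROI's temporal extent plus context on both sides (clipped to the valid
#' frame range).
#'
#' @slot frames Integer frame indices of the window.
#' @slot times Frame times in seconds (`(frames - 1) / frameRate`).
#' @slot dff Mean dF/F0 over the footprint, one value per window frame.
#' @slot footprint Integer matrix of `(row, col)` pixels averaged.
#' @slot window `(first, last)` frame of the window.
#' @slot roiExtent `(first, last)` frame touched by the ROI itself.
#'
#' @seealso [extractTrace()], [computeKinetics()]
#' @exportClass EventTrace
setClass("EventTrace",
  representation(
    frames = "integer", times = "numeric", dff = "numeric",
    footprint = "matrix", window = "integer", roiExtent = "integer"
  )
)

setValidity("EventTrace", function(object) {
  if (length(object@dff) != length(object@frames))
    return("'dff' and 'frames' must have equal length")
  if (anyNA(object@dff) || any(!is.finite(object@dff)))
    return("'dff' must be finite on the whole window")
  TRUE
})

#' Per-pixel background-noise model
#'
#' Temporal mean and standard deviation of every pixel, either estimated
#' from a recorded movie ([estimateNoiseModel()]) or generated from a
#' smooth synthetic cell on a background ([syntheticNoiseModel()]).
#'
#' @slot meanMap,stdMap Numeric matrices `(row, column)` in intensity units.
#' @slot source `"from_movie"` or `"synthetic"`.
#'
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(meanMap = "matrix", stdMap = "matrix", source = "character")
)

setValidity("NoiseModel", function(object) {
  if (!identical(dim(object@meanMap), dim(object@stdMap)))
    return("'meanMap' and 'stdMap' must share dimensions")
  if (any(object@stdMap < 0))
    return("'stdMap' must be non-negative")
  if (!object@source %in% c("from_movie", "synthetic"))
    return("'source' must be \"from_movie\" or \"synthetic\"")
  TRUE
})

#' Normalized event waveform template
#'
#' A discretely sampled, non-negative fluorescence time course with peak
#' value exactly 1, used to shape simulated events in time.
#'
#' @slot samples Waveform samples at `frameRate`, peak 1.
#' @slot frameRate Sampling rate in Hz.
#' @slot riseTau,decayTau Time constants (s) of the difference-of-
#'   exponentials default waveform.
#' @slot description Free-text provenance of the waveform.
#'
#' @seealso [makeEventTemplate()], [simulateMovie()]
#' @exportClass EventTemplate
setClass("EventTemplate",
  representation(
    samples = "numeric", frameRate = "numeric",
    riseTau = "numeric", decayTau = "numeric", description = "character"
  )
)

setValidity("EventTemplate", function(object) {
  s <- object@samples
  if (length(s) < 1L || anyNA(s)) return("'samples' must be non-empty and finite")
  if (any(s < 0)) return("'samples' must be non-negative")
  if (abs(max(s) - 1) > 1e-12) return("'samples' must peak at exactly 1")
  TRUE
})

#' Ground truth of a simulated movie
#'
#' @slot events `data.frame` with columns `event_id`, `frame`, `row`, `col`
#'   (1-based seed coordinates).
#' @slot snr Signal-to-noise ratio of the simulation.
#' @slot seed RNG seed used.
#' @slot params Full parameter echo of the simulation (including the usable
#'   frame range and the implied event rate).
#'
#' @seealso [simulateMovie()], [matchDetections()]
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    events = "data.frame", snr = "numeric", seed = "integer", params = "list"
  )
)

#' Result of matching detections to ground truth
#'
#' One-to-one greedy matching of detected ROI peaks to ground-truth seeds
#' within a Chebyshev spatial tolerance and a temporal tolerance.
#'
#' @slot pairs `data.frame` of matched pairs (`truth_id`, `roi`, `dt`,
#'   `dxy`).
#' @slot nTruth Number of ground-truth events in the denominator (after
#'   excluding events seeded where detection is impossible by construction).
#' @slot nExcluded Ground-truth events excluded from the denominator.
#' @slot nDetected Number of detected ROIs.
#' @slot nMatched Number of matched pairs.
#'
#' @seealso [matchDetections()], [tpr()]
#' @exportClass MatchResult
setClass("MatchResult",
  representation(
    pairs = "data.frame", nTruth = "integer", nExcluded = "integer",
    nDetected = "integer", nMatched = "integer"
  )
)

setValidity("MatchResult", function(object) {
  if (object@nMatched > min(object@nTruth, object@nDetected))
    return("'nMatched' cannot exceed min(nTruth, nDetected)")
  TRUE
})

#' True-positive rate as a function of SNR
#'
#' @slot points Aggregate `data.frame` (`snr`, `tpr`, `n`), one row per SNR,
#'   `tpr` the mean over replicates.
#' @slot replicates Per-run `data.frame` (`snr`, `replicate`, `seed`, `tpr`,
#'   `n_truth`, `n_detected`, `n_matched`).
#' @slot config Parameter echo of the sweep.
#'
#' @seealso [runSnrSweep()], [fitSigmoid()]
#' @exportClass BenchmarkCurve
setClass("BenchmarkCurve",
  representation(points = "data.frame", replicates = "data.frame",
                 config = "list")
)

setValidity("BenchmarkCurve", function(object) {
  p <- object@points
  if (is.unsorted(p$snr, strictly = TRUE))
    return("'points$snr' must be strictly increasing")
  if (any(p$tpr < 0 | p$tpr > 1))
    return("'tpr' must lie in [0, 1]")
  TRUE
})

#' Logistic fit of the TPR-vs-SNR curve
#'
#' The model is `tpr(snr) = a / (1 + exp(-(snr - x0) / b))`: `a` is the
#' maximum detection rate, `x0` the SNR of half-maximal performance
#' (where the curve equals `a/2`), and `b` the slope scale. The SNR at
#' which 99% of the maximum is reached is `x0 + b * log(99)`.
#'
#' @slot a Fitted asymptote, in (0, 1].
#' @slot x0 Half-maximum SNR.
#' @slot b Slope parameter, > 0.
#' @slot residual Root-mean-square residual of the fit.
#' @slot nPoints Number of points fitted.
#'
#' @seealso [fitSigmoid()], [snr99()], [tprAtHalf()]
#' @exportClass SigmoidFit
setClass("SigmoidFit",
  representation(a = "numeric", x0 = "numeric", b = "numeric",
                 residual = "numeric", nPoints = "integer")
)

setValidity("SigmoidFit", function(object) {
  if (object@a <= 0 || object@a > 1 + 1e-9)
    return("'a' must lie in (0, 1]")
  if (object@b <= 0)
    return("'b' must be > 0")
  TRUE
})
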