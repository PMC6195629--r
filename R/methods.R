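# Accessor and show methods.

#' @rdname accessors
setMethod("movieData", "MovieStack", function(object) object@data)

#' @rdname accessors
setMethod("meta", "MovieStack", function(object) object@meta)

#' @rdname accessors
setMethod("meta", "DffStack", function(object) object@meta)

#' @rdname accessors
setMethod("dffData", "DffStack", function(object) object@data)

#' @rdname accessors
setMethod("validFrom", "DffStack", function(object) object@validFrom)

#' @rdname accessors
setMethod("validFrom", "DetectionResult", function(object) object@validFrom)

#' @rdname accessors
setMethod("nVoxels", "Roi3D", function(object) nrow(object@voxels))

#' @rdname accessors
setMethod("tExtent", "Roi3D", function(object) range(object@voxels[, 1L]))

#' @rdname accessors
setMethod("peakOf", "Roi3D", function(object) object@peak)

#' @rdname accessors
setMethod("unionFootprint", "Roi3D", function(object) {
  fp <- unique(object@voxels[, 2:3, drop = FALSE])
  colnames(fp) <- c("row", "col")
  fp[order(fp[, 1L], fp[, 2L]), , drop = FALSE]
})

#' @rdname accessors
setMethod("footprintByFrame", "Roi3D", function(object) {
  v <- object@voxels
  lapply(split(seq_len(nrow(v)), v[, 1L]), function(i) {
    fp <- v[i, 2:3, drop = FALSE]
    colnames(fp) <- c("row", "col")
    fp
  })
})

#' @rdname accessors
setMethod("rois", "DetectionResult", function(object) object@rois)

#' @rdname accessors
setMethod("thresholds", "DetectionResult", function(object) object@thresholds)

#' @rdname accessors
setMethod("truthEvents", "GroundTruth", function(object) object@events)

#' @rdname accessors
setMethod("tpr", "MatchResult", function(object) {
  if (object@nTruth == 0L) return(NA_real_)
  object@nMatched / object@nTruth
})

#' @rdname accessors
setMethod("snr99", "SigmoidFit", function(object) object@x0 + object@b * log(99))

#' @rdname accessors
setMethod("tprAtHalf", "SigmoidFit", function(object) object@a / 2)

setMethod("show", "AcquisitionMeta", function(object) {
  cat(sprintf(
    "AcquisitionMeta: %d x %d px, %d frames @ %.2f Hz, %.3g um/px, %d-bit (%s-endian)\n",
    object@width, object@height, object@nFrames, object@frameRate,
    object@pixelSize, object@bitDepth, object@byteOrder))
})

setMethod("show", "MovieStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("MovieStack: %d frames of %d x %d px (%d-bit), range [%g, %g]\n",
              d[1L], d[2L], d[3L], object@meta@bitDepth,
              min(object@data), max(object@data)))
  show(object@meta)
})

setMethod("show", "DffStack", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "DffStack: %d frames of %d x %d px; valid from frame %d\n",
    d[1L], d[2L], d[3L], object@validFrom))
})

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig:\n")
  cat(sprintf("  Gaussian sigma: %g px spatial, %g frames temporal\n",
              object@sigmaSpatial, object@sigmaTemporal))
  cat(sprintf("  F0 window: t-%d ... t-%d (%d frames)\n",
              object@baselineWindow[1L], object@baselineWindow[2L],
              object@baselineWindow[1L] - object@baselineWindow[2L] + 1L))
  cat(sprintf("  threshold: median + %g x IQR per frame\n", object@thresholdK))
  cat(sprintf("  ROI filters: >= %d voxels, mask %s (%s mode), %d-connectivity\n",
              object@minVoxels, if (object@useMask) "on" else "off",
              object@maskMode, object@connectivity))
})

setMethod("show", "Roi3D", function(object) {
  te <- tExtent(object)
  cat(sprintf(
    "Roi3D: %d voxels, frames %d-%d, peak dF/F0 = %.4g at (t=%d, y=%d, x=%d)\n",
    nVoxels(object), te[1L], te[2L], object@peakDff,
    object@peak[1L], object@peak[2L], object@peak[3L]))
})

setMethod("show", "DetectionResult", function(object) {
  cat(sprintf("DetectionResult: %d accepted ROIs", length(object@rois)))
  if (length(object@rejected))
    cat(sprintf(" (%s rejected)",
                paste(sprintf("%d by %s", object@rejected,
                              names(object@rejected)), collapse = ", ")))
  cat(sprintf("; valid frames %d-%d\n",
              object@validFrom, length(object@thresholds)))
})

setMethod("show", "NoiseModel", function(object) {
  d <- dim(object@meanMap)
  cat(sprintf(
    "NoiseModel (%s): %d x %d px, mean %g-%g, std %g-%g\n",
    object@source, d[1L], d[2L],
    signif(min(object@meanMap), 4), signif(max(object@meanMap), 4),
    signif(min(object@stdMap), 4), signif(max(object@stdMap), 4)))
})

setMethod("show", "EventTemplate", function(object) {
  cat(sprintf("EventTemplate: %d samples @ %.2f Hz (%s)\n",
              length(object@samples), object@frameRate, object@description))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d events, SNR = %g, seed = %d\n",
              nrow(object@events), object@snr, object@seed))
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf(
    "MatchResult: %d/%d truth events matched (TPR = %.3f), %d detections, %d false positives",
    object@nMatched, object@nTruth, tpr(object), object@nDetected,
    object@nDetected - object@nMatched))
  if (object@nExcluded > 0L)
    cat(sprintf("; %d truth events excluded from the denominator",
                object@nExcluded))
  cat("\n")
})

setMethod("show", "BenchmarkCurve", function(object) {
  p <- object@points
  cat(sprintf(
    "BenchmarkCurve: %d SNR points in [%g, %g], %d runs total\n",
    nrow(p), min(p$snr), max(p$snr), nrow(object@replicates)))
})

setMethod("show", "SigmoidFit", function(object) {
  cat(sprintf(
    "SigmoidFit: tpr(snr) = %.3f / (1 + exp(-(snr - %.3f)/%.3f))\n",
    object@a, object@x0, object@b))
  cat(sprintf(
    "  half-max at SNR %.2f (TPR %.2f); 99%% of max at SNR %.2f; RMS residual %.3g\n",
    object@x0, tprAtHalf(object), snr99(object), object@residual))
})
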