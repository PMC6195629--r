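#' Accessors for package classes
#'
#' Small accessor generics: `movieData()` returns the intensity array of a
#' [MovieStack-class]; `meta()` its [AcquisitionMeta-class]; `dffData()`
#' and `validFrom()` the array and first valid frame of a
#' [DffStack-class]; `nVoxels()`, `tExtent()`, `peakOf()`,
#' `unionFootprint()` and `footprintByFrame()` describe an
#' [Roi3D-class]; `rois()` and `thresholds()` unpack a
#' [DetectionResult-class]; `truthEvents()` the seed table of a
#' [GroundTruth-class]; `tpr()` the true-positive rate of a
#' [MatchResult-class]; `snr99()` and `tprAtHalf()` derived quantities of
#' a [SigmoidFit-class].
#'
#' @param object An object of the documented class.
#' @return See each generic's description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("movieData", function(object) standardGeneric("movieData"))

#' @rdname accessors
#' @export
setGeneric("meta", function(object) standardGeneric("meta"))

#' @rdname accessors
#' @export
setGeneric("dffData", function(object) standardGeneric("dffData"))

#' @rdname accessors
#' @export
setGeneric("validFrom", function(object) standardGeneric("validFrom"))

#' @rdname accessors
#' @export
setGeneric("nVoxels", function(object) standardGeneric("nVoxels"))

#' @rdname accessors
#' @export
setGeneric("tExtent", function(object) standardGeneric("tExtent"))

#' @rdname accessors
#' @export
setGeneric("peakOf", function(object) standardGeneric("peakOf"))

#' @rdname accessors
#' @export
setGeneric("unionFootprint", function(object) standardGeneric("unionFootprint"))

#' @rdname accessors
#' @export
setGeneric("footprintByFrame", function(object) standardGeneric("footprintByFrame"))

#' @rdname accessors
#' @export
setGeneric("rois", function(object) standardGeneric("rois"))

#' @rdname accessors
#' @export
setGeneric("thresholds", function(object) standardGeneric("thresholds"))

#' @rdname accessors
#' @export
setGeneric("truthEvents", function(object) standardGeneric("truthEvents"))

#' @rdname accessors
#' @export
setGeneric("tpr", function(object) standardGeneric("tpr"))

#' @rdname accessors
#' @export
setGeneric("snr99", function(object) standardGeneric("snr99"))

#' @rdname accessors
#' @export
setGeneric("tprAtHalf", function(object) standardGeneric("tprAtHalf"))
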