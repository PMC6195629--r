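#' Construct a detection configuration
#'
#' See [FilterConfig-class] for the meaning and default of every field.
#'
#' @param sigmaSpatial,sigmaTemporal Gaussian sigmas (px, frames).
#' @param baselineWindow Integer pair `(far, near)` of baseline offsets.
#' @param thresholdK IQR multiplier of the per-frame threshold.
#' @param minVoxels Minimum ROI size in voxels.
#' @param useMask Reject ROIs outside the inclusion mask?
#' @param maskMode `"peak"` or `"any"` voxel membership.
#' @param connectivity 6, 18 or 26.
#' @param contextFrames Trace context margin (frames) per side.
#' @param baselineFrames Pre-peak frames averaged as the kinetics baseline.
#' @return A [FilterConfig-class].
#' @examples
#' filterConfig()
#' filterConfig(thresholdK = 4, useMask = FALSE)
#' @export
filterConfig <- function(sigmaSpatial = 3, sigmaTemporal = 2,
                         baselineWindow = c(15L, 5L), thresholdK = 3,
                         minVoxels = 2L, useMask = TRUE,
                         maskMode = c("peak", "any"), connectivity = 26L,
                         contextFrames = 30L, baselineFrames = 10L) {
  new("FilterConfig",
      sigmaSpatial = as.numeric(sigmaSpatial),
      sigmaTemporal = as.numeric(sigmaTemporal),
      baselineWindow = as.integer(baselineWindow),
      thresholdK = as.numeric(thresholdK),
      minVoxels = as.integer(minVoxels),
      useMask = isTRUE(useMask), maskMode = match.arg(maskMode),
      connectivity = as.integer(connectivity),
      contextFrames = as.integer(contextFrames),
      baselineFrames = as.integer(baselineFrames))
}

#' Read a detection configuration from a YAML file
#'
#' Recognized keys are the argument names of [filterConfig()]; unknown keys
#' raise an error. Keys absent from the file keep their defaults, and
#' entries of `overrides` win over the file.
#'
#' @param path Path of a YAML file, or `NULL` for pure defaults.
#' @param overrides Named list applied on top of the file.
#' @return A [FilterConfig-class].
#' @export
readFilterConfig <- function(path = NULL, overrides = list()) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  vals[names(overrides)] <- overrides
  known <- names(formals(filterConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown detection config keys: ", paste(bad, collapse = ", "))
  do.call(filterConfig, vals)
}

#' 3D Gaussian noise filter
#'
#' Separable Gaussian smoothing with sigma `(sigmaTemporal, sigmaSpatial,
#' sigmaSpatial)` along `(t, y, x)`. Edges are handled by replicating the
#' boundary samples, which avoids artificial dark borders that would
#' otherwise distort the per-frame intensity distribution used for
#' thresholding. The kernel is truncated at 4 sigma.
#'
#' @param stack A [MovieStack-class] or a bare 3D numeric array.
#' @param cfg A [FilterConfig-class].
#' @return A 3D numeric array of smoothed intensities, same shape.
#' @examples
#' m <- movieStack(array(100L, c(20, 8, 8)))
#' f <- gaussianFilter3d(m, filterConfig())
#' stopifnot(all(abs(f - 100) < 1e-9))
#' @export
gaussianFilter3d <- function(stack, cfg = filterConfig()) {
  arr <- if (is(stack, "MovieStack")) stack@data else stack
  stopifnot(length(dim(arr)) == 3L)
  arr <- convolveAxis3d(arr, gaussianKernel1d(cfg@sigmaTemporal), axis = 1L)
  arr <- convolveAxis3d(arr, gaussianKernel1d(cfg@sigmaSpatial), axis = 2L)
  convolveAxis3d(arr, gaussianKernel1d(cfg@sigmaSpatial), axis = 3L)
}

#' Moving-baseline dF/F0 transform
#'
#' For every pixel and frame `t`, the baseline `F0(t)` is the mean of that
#' pixel's (filtered) intensity on frames `t-far ... t-near` (defaults
#' 15 and 5: 11 strictly past samples), and `dF/F0 = (F - F0)/F0`. This
#' moving baseline highlights fast-onset transients and deliberately
#' suppresses slow drifts. Frames with an incomplete window (`t <= far`)
#' are marked invalid rather than computed with a shortened window, keeping
#' the baseline estimator's variance constant across frames.
#'
#' Baselines below `1e-6 x mean(filtered)` are floored at that value to
#' guard against division blow-ups on synthetic inputs; real camera data
#' carry positive offsets and never trigger the floor. A message reports
#' the number of floored baselines when any occur.
#'
#' @param filtered 3D numeric array from [gaussianFilter3d()] (or a
#'   [MovieStack-class], smoothed or not).
#' @param cfg A [FilterConfig-class] (uses `baselineWindow`).
#' @param meta Optional [AcquisitionMeta-class] carried into the result;
#'   taken from `filtered` when it is a [MovieStack-class].
#' @return A [DffStack-class] with `validFrom = far + 1`.
#' @examples
#' arr <- array(100, c(40, 2, 2)); arr[30:40, , ] <- 110
#' d <- computeDff(arr, filterConfig(sigmaSpatial = 0, sigmaTemporal = 0))
#' stopifnot(abs(dffData(d)[30, 1, 1] - 0.1) < 1e-12)
#' @export
computeDff <- function(filtered, cfg = filterConfig(), meta = NULL) {
  if (is(filtered, "MovieStack")) {
    if (is.null(meta)) meta <- filtered@meta
    filtered <- filtered@data
  }
  d <- dim(filtered)
  far <- cfg@baselineWindow[1L]
  near <- cfg@baselineWindow[2L]
  if (d[1L] <= far)
    stop(sprintf("need more than %d frames for a %d-frame-deep baseline window",
                 far, far))
  if (is.null(meta))
    meta <- acquisitionMeta(width = d[3L], height = d[2L], nFrames = d[1L])
  M <- asFramePixelMatrix(filtered)
  win <- far - near + 1L
  tt <- (far + 1L):d[1L]
  # F0 row i covers frames i ... i + win - 1, i.e. frame t = i + far
  F0 <- bandConvolve(M[seq_len(d[1L] - near), , drop = FALSE],
                     rep(1 / win, win), mode = "valid")
  eps <- 1e-6 * mean(filtered)
  nFloored <- sum(F0 < eps)
  if (nFloored > 0L) {
    F0[F0 < eps] <- eps
    message(sprintf("computeDff: floored %d non-positive baseline values", nFloored))
  }
  dff <- matrix(NA_real_, d[1L], ncol(M))
  dff[tt, ] <- (M[tt, , drop = FALSE] - F0) / F0
  new("DffStack", data = array(dff, dim = d), validFrom = far + 1L,
      meta = meta)
}

#' Inclusion mask of above-average pixels
#'
#' A pixel is accepted when its temporal-mean intensity exceeds the grand
#' mean of the temporal-mean image. On fluorescence recordings this
#' approximates the labelled cell area and is used to discard events
#' detected outside cell structure. A perfectly constant movie has no
#' above-average pixels; the degenerate case falls back to an all-`TRUE`
#' mask with a warning.
#'
#' @param stack A [MovieStack-class] or bare 3D array (raw, not dF/F0).
#' @return Logical matrix `(row, column)`.
#' @export
computeInclusionMask <- function(stack) {
  arr <- if (is(stack, "MovieStack")) stack@data else stack
  d <- dim(arr)
  tm <- matrix(colMeans(asFramePixelMatrix(arr)), d[2L], d[3L])
  accept <- tm > mean(tm)
  if (!any(accept)) {
    warning("constant movie: inclusion mask is empty, falling back to all-TRUE")
    accept[] <- TRUE
  }
  accept
}

#' Mono-exponential photobleaching correction
#'
#' Fits `m(t) = a * exp(-t / tau) + c` to the per-frame mean intensity
#' (least squares, `t` counted from 0) and subtracts the decaying component
#' `a * exp(-t / tau)` from every pixel of frame `t`. This correction
#' belongs to the manual-comparison pathway; the moving-baseline dF/F0 of
#' the automated pipeline is insensitive to slow bleaching and does not use
#' it.
#'
#' @param stack A [MovieStack-class] or bare 3D array with >= 10 frames.
#' @return A list with `corrected` (3D numeric array) and `fit` (named
#'   vector `a`, `tau`, `c`; `a = 0`, `tau = NA` when the movie shows no
#'   decaying trend or the fit fails, in which case the data pass through
#'   unchanged with a warning for the failure case).
#' @export
bleachCorrect <- function(stack) {
  arr <- if (is(stack, "MovieStack")) stack@data else stack
  d <- dim(arr)
  if (d[1L] < 10L) stop("bleach correction needs at least 10 frames")
  m <- rowMeans(asFramePixelMatrix(arr))
  t0 <- seq_len(d[1L]) - 1
  if (stats::sd(m) < 1e-12 * max(abs(mean(m)), 1)) {
    return(list(corrected = arr,
                fit = c(a = 0, tau = NA_real_, c = mean(m))))
  }
  cStart <- min(m)
  aStart <- max(m[1L] - cStart, 1e-3 * max(m))
  tauStart <- d[1L] / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(m ~ a * exp(-t0 / tau) + c,
                      start = list(a = aStart, tau = tauStart, c = cStart),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("bleach fit did not converge; returning data unchanged")
    return(list(corrected = arr, fit = c(a = 0, tau = NA_real_, c = mean(m))))
  }
  p <- stats::coef(fit)
  bleach <- p[["a"]] * exp(-t0 / p[["tau"]])
  corrected <- arr - array(bleach, dim = d)  # recycles along the time axis
  list(corrected = corrected, fit = c(a = p[["a"]], tau = p[["tau"]],
                                      c = p[["c"]]))
}
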