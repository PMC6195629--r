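#' Match detected ROIs to ground-truth events
#'
#' A truth seed and a detected ROI peak are compatible when they lie
#' within `maxDxy` pixels in each spatial axis (Chebyshev metric) and
#' within `maxDt` frames in time. Matching is one-to-one and greedy by
#' increasing spatio-temporal distance (Euclidean over `(dt, dy, dx)`),
#' ties broken by earlier truth id then earlier ROI — the conservative
#' reading of a true positive, where several detections cannot claim the
#' same event. Truth events seeded outside the range where detection is
#' possible by construction (the baseline warm-up, or closer than one
#' template length to the end) are excluded from the denominator and
#' counted in `nExcluded`; the default simulator never seeds there.
#'
#' @param truth A [GroundTruth-class].
#' @param result A [DetectionResult-class] (or a `data.frame` of detected
#'   peaks with columns `peak_t`, `peak_y`, `peak_x`).
#' @param maxDxy Spatial tolerance, px (0.4 um at the reference
#'   calibration).
#' @param maxDt Temporal tolerance, frames (+/-348 ms at 28.77 Hz).
#' @return A [MatchResult-class].
#' @export
matchDetections <- function(truth, result, maxDxy = 1L, maxDt = 10L) {
  stopifnot(is(truth, "GroundTruth"))
  det <- if (is.data.frame(result)) result else roiTable(result)
  ev <- truth@events
  usable <- truth@params$usableFrames
  if (!is.null(usable)) {
    ok <- ev$frame >= usable[1L] & ev$frame <= usable[2L]
  } else ok <- rep(TRUE, nrow(ev))
  nExcluded <- sum(!ok)
  ev <- ev[ok, , drop = FALSE]
  nTruth <- nrow(ev)
  nDet <- nrow(det)
  emptyPairs <- data.frame(truth_id = integer(), roi = integer(),
                           dt = integer(), dxy = integer())
  if (nTruth == 0L || nDet == 0L) {
    return(new("MatchResult", pairs = emptyPairs,
               nTruth = as.integer(nTruth), nExcluded = as.integer(nExcluded),
               nDetected = as.integer(nDet), nMatched = 0L))
  }
  dt <- outer(ev$frame, det$peak_t, "-")
  dy <- outer(ev$row, det$peak_y, "-")
  dx <- outer(ev$col, det$peak_x, "-")
  compat <- abs(dt) <= maxDt & pmax(abs(dy), abs(dx)) <= maxDxy
  cand <- which(compat, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(new("MatchResult", pairs = emptyPairs,
               nTruth = as.integer(nTruth), nExcluded = as.integer(nExcluded),
               nDetected = as.integer(nDet), nMatched = 0L))
  }
  dist <- sqrt(dt[cand]^2 + dy[cand]^2 + dx[cand]^2)
  ord <- order(dist, cand[, 1L], cand[, 2L])
  cand <- cand[ord, , drop = FALSE]
  truthUsed <- logical(nTruth)
  roiUsed <- logical(nDet)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ti <- cand[i, 1L]; ri <- cand[i, 2L]
    if (!truthUsed[ti] && !roiUsed[ri]) {
      truthUsed[ti] <- TRUE
      roiUsed[ri] <- TRUE
      keep[i] <- TRUE
    }
  }
  m <- cand[keep, , drop = FALSE]
  pairs <- data.frame(
    truth_id = ev$event_id[m[, 1L]],
    roi = if ("roi" %in% names(det)) det$roi[m[, 2L]] else m[, 2L],
    dt = dt[m], dxy = pmax(abs(dy[m]), abs(dx[m])))
  new("MatchResult", pairs = pairs,
      nTruth = as.integer(nTruth), nExcluded = as.integer(nExcluded),
      nDetected = as.integer(nDet), nMatched = as.integer(nrow(pairs)))
}

#' Sweep SNR and measure the detection rate
#'
#' For every SNR on the grid and every replicate, simulates a movie (seed
#' derived deterministically from `baseSeed` and the grid/replicate
#' indices), runs the full detection pipeline and matches detections to
#' the ground truth. The curve is fully reproducible from `baseSeed`.
#'
#' @param snrGrid Numeric vector of SNR values (need not be sorted;
#'   duplicated values are an error).
#' @param noise A [NoiseModel-class].
#' @param mask Logical cell mask used for seeding events.
#' @param template An [EventTemplate-class].
#' @param cfg Detection [FilterConfig-class].
#' @param nEvents,eventRate,nFrames,frameRate Passed to [simulateMovie()].
#' @param replicates Simulations per SNR value.
#' @param baseSeed Base RNG seed; run `(i, j)` uses
#'   `baseSeed + 1009 * i + j`.
#' @param maxDxy,maxDt Matching tolerances, see [matchDetections()].
#' @param verbose Print one progress line per SNR value.
#' @return A [BenchmarkCurve-class].
#' @seealso [fitSigmoid()], [performanceReport()]
#' @export
runSnrSweep <- function(snrGrid = seq(0, 7, by = 0.25),
                        noise = NULL, mask = NULL,
                        template = makeEventTemplate(),
                        cfg = filterConfig(),
                        nEvents = 100L, eventRate = 10, nFrames = 600L,
                        frameRate = 28.77, replicates = 3L, baseSeed = 1L,
                        maxDxy = 1L, maxDt = 10L, verbose = FALSE) {
  if (anyDuplicated(snrGrid)) stop("'snrGrid' contains duplicated values")
  if (is.null(noise) || is.null(mask)) {
    syn <- syntheticNoiseModel()
    if (is.null(noise)) noise <- syn$noise
    if (is.null(mask)) mask <- syn$mask
  }
  ord <- order(snrGrid)
  grid <- snrGrid[ord]
  reps <- vector("list", length(grid) * replicates)
  n <- 0L
  for (i in seq_along(grid)) {
    for (j in seq_len(replicates)) {
      seed <- as.integer(baseSeed + 1009L * i + j)
      sim <- suppressMessages(simulateMovie(
        noise, mask, template, snr = grid[i], nEvents = nEvents,
        eventRate = eventRate, nFrames = nFrames, frameRate = frameRate,
        warmupFrames = cfg@baselineWindow[1L], seed = seed))
      res <- detectEvents(sim$movie, cfg)
      mr <- matchDetections(sim$truth, res, maxDxy = maxDxy, maxDt = maxDt)
      n <- n + 1L
      reps[[n]] <- data.frame(
        snr = grid[i], replicate = j, seed = seed, tpr = tpr(mr),
        n_truth = mr@nTruth, n_detected = mr@nDetected,
        n_matched = mr@nMatched)
    }
    if (verbose)
      message(sprintf("SNR %.2f: mean TPR %.3f", grid[i],
                      mean(vapply(reps[(n - replicates + 1L):n],
                                  function(r) r$tpr, 0))))
  }
  repDf <- do.call(rbind, reps)
  points <- do.call(rbind, lapply(split(repDf, repDf$snr), function(g)
    data.frame(snr = g$snr[1L], tpr = mean(g$tpr), n = nrow(g))))
  points <- points[order(points$snr), , drop = FALSE]
  rownames(points) <- NULL
  new("BenchmarkCurve", points = points, replicates = repDf,
      config = list(snrGrid = grid, nEvents = nEvents,
                    eventRate = eventRate, nFrames = nFrames,
                    frameRate = frameRate, replicates = replicates,
                    baseSeed = baseSeed, maxDxy = maxDxy, maxDt = maxDt,
                    template = template@description))
}

#' Fit a logistic curve to the TPR-vs-SNR points
#'
#' Least-squares fit of `tpr(snr) = a / (1 + exp(-(snr - x0) / b))` to the
#' per-replicate points, with `a` bounded in (0, 1] and `b > 0`
#' (Levenberg-Marquardt). Derived quantities: half-maximal performance is
#' reached at `x0` with TPR `a/2`, and 99% of the maximum at
#' `x0 + b * log(99)` (exactly, by the algebra of the logistic).
#'
#' @param curve A [BenchmarkCurve-class], or a `data.frame` with columns
#'   `snr` and `tpr`.
#' @return A [SigmoidFit-class].
#' @export
fitSigmoid <- function(curve) {
  df <- if (is(curve, "BenchmarkCurve")) curve@replicates else curve
  stopifnot(all(c("snr", "tpr") %in% names(df)))
  if (length(unique(df$snr)) < 4L)
    stop("need at least 4 distinct SNR values to fit the sigmoid")
  aStart <- max(df$tpr)
  if (aStart <= 0) stop("all TPR values are zero; nothing to fit")
  agg <- tapply(df$tpr, df$snr, mean)
  snrs <- as.numeric(names(agg))
  x0Start <- snrs[which.min(abs(agg - aStart / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      tpr ~ a / (1 + exp(-(snr - x0) / b)), data = df,
      start = list(a = min(aStart, 0.99), x0 = x0Start, b = 0.5),
      lower = c(1e-6, -Inf, 1e-6), upper = c(1, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("sigmoid fit did not converge: ", conditionMessage(e),
           call. = FALSE))
  p <- stats::coef(fit)
  new("SigmoidFit", a = unname(p["a"]), x0 = unname(p["x0"]),
      b = unname(p["b"]),
      residual = sqrt(mean(stats::resid(fit)^2)),
      nPoints = nrow(df))
}

#' Write the benchmark report bundle
#'
#' Writes `curve.csv` (aggregate points), `replicates.csv` (per-run
#' results), `fit.json` (fit parameters and derived quantities) and
#' `performance.png` (TPR vs SNR with the fitted curve) into a directory.
#'
#' @param fit A [SigmoidFit-class].
#' @param curve The [BenchmarkCurve-class] it was fitted to.
#' @param path Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
performanceReport <- function(fit, curve, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  curvePath <- file.path(path, "curve.csv")
  repPath <- file.path(path, "replicates.csv")
  fitPath <- file.path(path, "fit.json")
  plotPath <- file.path(path, "performance.png")
  utils::write.csv(curve@points, curvePath, row.names = FALSE)
  utils::write.csv(curve@replicates, repPath, row.names = FALSE)
  jsonlite::write_json(
    list(a = fit@a, x0 = fit@x0, b = fit@b, snr_99 = snr99(fit),
         tpr_at_half = tprAtHalf(fit), residual = fit@residual,
         n_points = fit@nPoints),
    fitPath, auto_unbox = TRUE, digits = NA)
  grDevices::png(plotPath, width = 640, height = 480)
  rep <- curve@replicates
  graphics::plot(rep$snr, rep$tpr, pch = 16, cex = 0.6,
                 col = grDevices::adjustcolor("steelblue", 0.6),
                 xlab = "SNR", ylab = "true positive rate", ylim = c(0, 1),
                 main = "Detection performance vs SNR")
  xs <- seq(min(rep$snr), max(rep$snr), length.out = 300)
  graphics::lines(xs, fit@a / (1 + exp(-(xs - fit@x0) / fit@b)),
                  col = "red", lwd = 2)
  graphics::abline(v = fit@x0, lty = 3)
  grDevices::dev.off()
  invisible(c(curvePath, repPath, fitPath, plotPath))
}

#' Read a fit report back into a SigmoidFit
#'
#' @param path Path of a `fit.json` written by [performanceReport()].
#' @return A [SigmoidFit-class].
#' @export
readSigmoidFit <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SigmoidFit", a = j$a, x0 = j$x0, b = j$b,
      residual = j$residual, nPoints = as.integer(j$n_points))
}
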