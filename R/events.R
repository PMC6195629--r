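#' Extract the dF/F0 trace of one ROI
#'
#' The trace is the per-frame mean dF/F0 over the ROI's union footprint
#' (the union of all per-frame pixel sets, a fixed region over the whole
#' window), on frames `t_start - context ... t_end + context`, clipped to
#' the valid frame range of the stack.
#'
#' @param roi An [Roi3D-class].
#' @param dff The [DffStack-class] the ROI was detected on.
#' @param contextFrames Context margin per side, in frames (~1 s at the
#'   default of 30 frames and 28.77 Hz, enough for the baseline and a full
#'   GCaMP6f decay).
#' @return An [EventTrace-class].
#' @export
extractTrace <- function(roi, dff, contextFrames = 30L) {
  stopifnot(is(roi, "Roi3D"), is(dff, "DffStack"))
  d <- dim(dff@data)
  te <- tExtent(roi)
  first <- max(dff@validFrom, te[1L] - contextFrames)
  last <- min(d[1L], te[2L] + contextFrames)
  if (first > last) stop("trace window lies outside the valid frame range")
  fp <- unionFootprint(roi)
  frames <- first:last
  idx <- cbind(rep(frames, each = nrow(fp)),
               rep(fp[, 1L], length(frames)),
               rep(fp[, 2L], length(frames)))
  vals <- matrix(dff@data[idx], nrow(fp), length(frames))
  new("EventTrace",
      frames = as.integer(frames),
      times = (frames - 1) / dff@meta@frameRate,
      dff = colMeans(vals), footprint = fp,
      window = as.integer(c(first, last)), roiExtent = as.integer(te))
}

# Fractional-index crossing of `level` on the rising flank nearest the
# peak: scan backwards from the peak for the last sample <= level and
# interpolate between it and its successor. NA when the flank never
# crosses inside the window.
crossingBefore <- function(y, peak, level) {
  i <- peak - 1L
  while (i >= 1L) {
    if (y[i] <= level) return(interpCrossing(y, i, level))
    i <- i - 1L
  }
  NA_real_
}

# Symmetric crossing on the falling flank after the peak.
crossingAfter <- function(y, peak, level) {
  i <- peak + 1L
  while (i <= length(y)) {
    if (y[i] <= level) return(interpCrossing(y, i - 1L, level))
    i <- i + 1L
  }
  NA_real_
}

#' Kinetic parameters of an event trace
#'
#' The baseline is the mean of the first `baselineFrames` samples of the
#' pre-peak context (fewer if the window is shorter); the amplitude is
#' peak minus baseline. The 10-90% rise time, 90-10% decay time and FWHM
#' are measured between level crossings located with sub-frame precision
#' by linear interpolation between the two samples straddling each level,
#' on the flank nearest the peak. A flank that never crosses a required
#' level inside the window leaves that field `NA` (flagged, never
#' imputed); the event itself is retained.
#'
#' @param trace An [EventTrace-class] (or a bare numeric dF/F0 vector).
#' @param frameRate Frames per second, used to convert frame-grid
#'   crossings to seconds.
#' @param baselineFrames Pre-peak context samples averaged as baseline.
#' @return A one-row `data.frame`: `baseline`, `amplitude`,
#'   `rise_time_s`, `decay_time_s`, `fwhm_s`, `peak_frame` (index within
#'   the window), `peak_time_s` (absolute, for [EventTrace-class] input).
#' @examples
#' # symmetric triangular peak on a flat baseline
#' tri <- c(rep(0, 20), seq(0.1, 1, by = 0.1), seq(0.9, 0, by = -0.1))
#' computeKinetics(tri, frameRate = 28.77)$fwhm_s * 28.77  # 10 frames
#' @export
computeKinetics <- function(trace, frameRate = 28.77, baselineFrames = 10L) {
  if (is(trace, "EventTrace")) {
    y <- trace@dff
    absFrame0 <- trace@frames[1L]
  } else {
    y <- as.numeric(trace)
    absFrame0 <- 1L
  }
  stopifnot(length(y) >= 2L, frameRate > 0)
  peak <- which.max(y)
  nPre <- min(baselineFrames, peak - 1L)
  baseline <- if (nPre >= 1L) mean(y[seq_len(nPre)]) else y[1L]
  amplitude <- y[peak] - baseline
  per <- 1 / frameRate
  if (amplitude <= 0) {
    return(data.frame(baseline = baseline, amplitude = amplitude,
                      rise_time_s = NA_real_, decay_time_s = NA_real_,
                      fwhm_s = NA_real_, peak_frame = absFrame0 + peak - 1L,
                      peak_time_s = (absFrame0 + peak - 2L) * per))
  }
  lv <- baseline + amplitude * c(0.1, 0.5, 0.9)
  r10 <- crossingBefore(y, peak, lv[1L])
  r50 <- crossingBefore(y, peak, lv[2L])
  r90 <- crossingBefore(y, peak, lv[3L])
  f90 <- crossingAfter(y, peak, lv[3L])
  f50 <- crossingAfter(y, peak, lv[2L])
  f10 <- crossingAfter(y, peak, lv[1L])
  data.frame(
    baseline = baseline, amplitude = amplitude,
    rise_time_s = (r90 - r10) * per,
    decay_time_s = (f10 - f90) * per,
    fwhm_s = (f50 - r50) * per,
    peak_frame = absFrame0 + peak - 1L,
    peak_time_s = (absFrame0 + peak - 2L) * per)
}

#' 2D area of an ROI
#'
#' The 2D area of a time-varying ROI is taken at its peak frame:
#' `|footprint at peak frame| * pixelSize^2` square micrometres.
#'
#' @param roi An [Roi3D-class].
#' @param pixelSize Pixel side length in micrometres (0.4 um at the
#'   reference calibration, so one pixel covers 0.16 um^2).
#' @return Area in um^2.
#' @export
computeArea <- function(roi, pixelSize = 0.4) {
  stopifnot(is(roi, "Roi3D"))
  sum(roi@voxels[, 1L] == roi@peak[1L]) * pixelSize^2
}

#' Build the event-record table of a detection run
#'
#' Extracts every accepted ROI's trace and kinetics and assembles the full
#' event table: identity, peak coordinates, kinetic parameters, peak-frame
#' area and the integrated amplitude `amplitude * area_2d` (dF/F0 x um^2).
#' The `class_label` and `verdict` columns are curator metadata, initially
#' `""` and `"accept"`, editable through the gallery CSV
#' ([exportGallery()], [importCuration()]).
#'
#' @param result A [DetectionResult-class].
#' @param dff The [DffStack-class] it was computed on.
#' @return A `data.frame`, one row per event.
#' @seealso [summarizeEvents()], [sortRois()]
#' @export
eventRecords <- function(result, dff) {
  stopifnot(is(result, "DetectionResult"), is(dff, "DffStack"))
  m <- dff@meta
  cfg <- result@config
  rois <- result@rois
  if (!length(rois)) {
    out <- data.frame(roi = integer(), peak_t = integer(), peak_y = integer(),
                      peak_x = integer(), peak_dff = numeric(),
                      n_voxels = integer(), baseline = numeric(),
                      amplitude = numeric(), rise_time_s = numeric(),
                      decay_time_s = numeric(), fwhm_s = numeric(),
                      area_um2 = numeric(), integrated_amplitude = numeric(),
                      peak_time_s = numeric(), verdict = character(),
                      class_label = character())
    return(out)
  }
  rows <- lapply(seq_along(rois), function(i) {
    r <- rois[[i]]
    tr <- extractTrace(r, dff, cfg@contextFrames)
    k <- computeKinetics(tr, m@frameRate, cfg@baselineFrames)
    area <- computeArea(r, m@pixelSize)
    pk <- unname(r@peak)
    data.frame(
      roi = i, peak_t = pk[1L], peak_y = pk[2L], peak_x = pk[3L],
      peak_dff = r@peakDff, n_voxels = nVoxels(r),
      baseline = k$baseline, amplitude = k$amplitude,
      rise_time_s = k$rise_time_s, decay_time_s = k$decay_time_s,
      fwhm_s = k$fwhm_s, area_um2 = area,
      integrated_amplitude = k$amplitude * area,
      peak_time_s = k$peak_time_s,
      verdict = "accept", class_label = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Event class vocabulary
#'
#' The nine curator-assignable event classes: five named kinetic classes
#' plus four user-definable slots. Classification is visual-inspection
#' metadata only; the package assigns no class automatically.
#'
#' @return Character vector of the nine class names.
#' @export
eventClasses <- function() {
  c("FastSingle", "FastComplex", "SlowSingle", "SlowComplex",
    "SlowFastComplex", "UserClass1", "UserClass2", "UserClass3", "UserClass4")
}

#' Fixed-ROI (manual-style) trace analysis
#'
#' Analyses a fixed 2D pixel set the way a manual workflow would, for
#' comparison with the automated pipeline. In `"assisted"` mode the
#' Gaussian-filtered movie is averaged over the ROI per frame and the
#' moving-baseline dF/F0 plus interpolated peak kinetics are applied as in
#' the automated pipeline. In `"manual"` mode the movie is
#' bleach-corrected, averaged over the ROI, `F0` is the mean of the last
#' 25 trace points, the baseline is the mean of the 10 points starting 50
#' frames before the peak, the amplitude is the dF/F0 maximum minus that
#' baseline, and the FWHM is read off at the data points nearest the
#' half-maximum on each flank (no interpolation).
#'
#' @param stack A [MovieStack-class].
#' @param roi2d Integer matrix of `(row, col)` pixels.
#' @param mode `"assisted"` or `"manual"`.
#' @param cfg A [FilterConfig-class] (assisted mode).
#' @return A one-row `data.frame` with `baseline`, `amplitude`,
#'   `rise_time_s`, `decay_time_s`, `fwhm_s`, `peak_frame`, `peak_time_s`
#'   (`rise`/`decay` are `NA` in manual mode, which does not define them),
#'   plus the trace as attribute `"trace"`.
#' @export
fixedRoiAnalysis <- function(stack, roi2d, mode = c("assisted", "manual"),
                             cfg = filterConfig()) {
  stopifnot(is(stack, "MovieStack"))
  mode <- match.arg(mode)
  roi2d <- as.matrix(roi2d)
  d <- dim(stack@data)
  if (any(roi2d[, 1L] < 1L | roi2d[, 1L] > d[2L] |
          roi2d[, 2L] < 1L | roi2d[, 2L] > d[3L]))
    stop("roi2d lies outside the image bounds")
  per <- 1 / stack@meta@frameRate
  roiMean <- function(arr) {
    idx <- cbind(rep(seq_len(d[1L]), each = nrow(roi2d)),
                 rep(roi2d[, 1L], d[1L]), rep(roi2d[, 2L], d[1L]))
    colMeans(matrix(arr[idx], nrow(roi2d), d[1L]))
  }
  if (mode == "assisted") {
    tr <- roiMean(gaussianFilter3d(stack, cfg))
    far <- cfg@baselineWindow[1L]; near <- cfg@baselineWindow[2L]
    if (length(tr) <= far) stop("trace too short for the baseline window")
    F0 <- vapply((far + 1L):length(tr), function(t)
      mean(tr[(t - far):(t - near)]), 0)
    dffTr <- (tr[(far + 1L):length(tr)] - F0) / F0
    k <- computeKinetics(dffTr, stack@meta@frameRate, cfg@baselineFrames)
    k$peak_frame <- k$peak_frame + far
    k$peak_time_s <- (k$peak_frame - 1L) * per
    attr(k, "trace") <- dffTr
    return(k)
  }
  # manual mode
  corrected <- bleachCorrect(stack)$corrected
  tr <- roiMean(corrected)
  if (length(tr) < 25L) stop("manual mode needs a trace of at least 25 points")
  F0 <- mean(utils::tail(tr, 25L))
  if (F0 <= 0) stop("manual F0 (mean of last 25 points) is not positive")
  dffTr <- (tr - F0) / F0
  peak <- which.max(dffTr)
  bStart <- peak - 50L
  if (bStart < 1L) {
    warning("peak closer than 50 frames to the start; baseline taken from the first 10 points")
    bStart <- 1L
  }
  baseline <- mean(dffTr[bStart:min(bStart + 9L, length(dffTr))])
  amplitude <- dffTr[peak] - baseline
  fwhm <- NA_real_
  if (amplitude > 0) {
    half <- baseline + amplitude / 2
    r <- crossingBefore(dffTr, peak, half)
    f <- crossingAfter(dffTr, peak, half)
    if (!is.na(r) && !is.na(f)) fwhm <- (round(f) - round(r)) * per
  }
  out <- data.frame(baseline = baseline, amplitude = amplitude,
                    rise_time_s = NA_real_, decay_time_s = NA_real_,
                    fwhm_s = fwhm, peak_frame = peak,
                    peak_time_s = (peak - 1L) * per)
  attr(out, "trace") <- dffTr
  out
}

#' Sort events or ROIs by salience
#'
#' Stable descending sort by the chosen key; ties are broken by earlier
#' peak frame, then lower ROI id, so that repeated runs order identically.
#'
#' @param x A `data.frame` from [eventRecords()] / [roiTable()], or a list
#'   of [Roi3D-class] (which supports the `peak_dff` and `n_voxels` keys).
#' @param by `"peak_dff"`, `"n_voxels"` or `"integrated_amplitude"`.
#' @return The reordered input.
#' @export
sortRois <- function(x, by = c("peak_dff", "n_voxels",
                               "integrated_amplitude")) {
  by <- match.arg(by)
  if (is.data.frame(x)) {
    if (!by %in% names(x))
      stop(sprintf("column '%s' not present in the table", by))
    ord <- order(-x[[by]], x$peak_t, x$roi)
    return(x[ord, , drop = FALSE])
  }
  stopifnot(all(vapply(x, is, TRUE, "Roi3D")))
  key <- switch(by,
    peak_dff = vapply(x, function(r) r@peakDff, 0),
    n_voxels = vapply(x, nVoxels, 0L),
    stop("'integrated_amplitude' requires an event-record table"))
  peakT <- vapply(x, function(r) r@peak[1L], 0L)
  x[order(-key, peakT, seq_along(x))]
}

#' Two-level event summary
#'
#' Descriptive parameters are first computed per event, then averaged per
#' cell (recording), and the per-cell means are averaged for the overall
#' mean with its SEM over cells. The event frequency of a cell is its
#' event count divided by the analysed duration. Events with
#' `verdict == "reject"` are excluded.
#'
#' @param records Event `data.frame` from [eventRecords()] with an added
#'   `cell` column naming the recording each event belongs to.
#' @param durations Named numeric vector: analysed duration (s) per cell.
#'   Cells without events still contribute zero frequency.
#' @return A list with `perCell` (one row per cell: `n_events`,
#'   `frequency_hz` and per-parameter means) and `overall` (mean and SEM
#'   over cells for each column).
#' @export
summarizeEvents <- function(records, durations) {
  if (is.null(names(durations)) || any(!nzchar(names(durations))))
    stop("'durations' must be a named vector (seconds per cell)")
  if (any(durations <= 0)) stop("durations must be positive")
  if (!"cell" %in% names(records))
    stop("'records' needs a 'cell' column assigning events to recordings")
  if ("verdict" %in% names(records))
    records <- records[records$verdict != "reject", , drop = FALSE]
  unknown <- setdiff(unique(records$cell), names(durations))
  if (length(unknown))
    stop("events reference cells without a duration: ",
         paste(unknown, collapse = ", "))
  params <- intersect(
    c("amplitude", "rise_time_s", "decay_time_s", "fwhm_s", "area_um2",
      "integrated_amplitude"), names(records))
  cells <- names(durations)
  perCell <- do.call(rbind, lapply(cells, function(cl) {
    ev <- records[records$cell == cl, , drop = FALSE]
    means <- vapply(params, function(p)
      if (nrow(ev)) mean(ev[[p]], na.rm = TRUE) else NA_real_, 0)
    cbind(data.frame(cell = cl, n_events = nrow(ev),
                     duration_s = unname(durations[cl]),
                     frequency_hz = nrow(ev) / unname(durations[cl])),
          as.data.frame(as.list(means)))
  }))
  num <- c("n_events", "frequency_hz", params)
  overall <- data.frame(
    parameter = num,
    mean = vapply(num, function(p) mean(perCell[[p]], na.rm = TRUE), 0),
    sem = vapply(num, function(p) {
      v <- perCell[[p]][!is.na(perCell[[p]])]
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
    }, 0), row.names = NULL)
  list(perCell = perCell, overall = overall)
}

#' Export an event gallery for visual curation
#'
#' Replaces interactive inspection with static artifacts: for each event
#' (sorted by descending peak dF/F0) a PNG montage — raw crop, dF/F0 crop
#' and the event trace — plus one `labels.csv` with columns `roi`,
#' `verdict` (`accept`/`reject`) and `class_label` that a curator can edit
#' and re-import with [importCuration()].
#'
#' @param records Event table from [eventRecords()].
#' @param result The [DetectionResult-class].
#' @param dff The [DffStack-class].
#' @param stack The raw [MovieStack-class].
#' @param path Output directory (created if needed).
#' @param cropHalf Half-size of the spatial crop, px.
#' @return Invisibly, the paths of the written files.
#' @export
exportGallery <- function(records, result, dff, stack, path, cropHalf = 12L) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ord <- sortRois(records, "peak_dff")
  d <- dim(dff@data)
  files <- character(0)
  for (i in seq_len(nrow(ord))) {
    ev <- ord[i, ]
    roi <- result@rois[[ev$roi]]
    ys <- max(1L, ev$peak_y - cropHalf):min(d[2L], ev$peak_y + cropHalf)
    xs <- max(1L, ev$peak_x - cropHalf):min(d[3L], ev$peak_x + cropHalf)
    tr <- extractTrace(roi, dff, result@config@contextFrames)
    f <- file.path(path, sprintf("event_%03d_roi_%03d.png", i, ev$roi))
    grDevices::png(f, width = 900, height = 320)
    op <- graphics::par(mfrow = c(1, 3), mar = c(3, 3, 2, 1))
    rawCrop <- stack@data[ev$peak_t, ys, xs]
    graphics::image(xs, ys, t(rawCrop)[, rev(seq_along(ys)), drop = FALSE],
                    col = grDevices::gray.colors(256), asp = 1,
                    main = sprintf("raw, frame %d", ev$peak_t),
                    xlab = "", ylab = "")
    dffCrop <- dff@data[ev$peak_t, ys, xs]
    graphics::image(xs, ys, t(dffCrop)[, rev(seq_along(ys)), drop = FALSE],
                    col = grDevices::hcl.colors(256, "viridis"), asp = 1,
                    main = "dF/F0", xlab = "", ylab = "")
    graphics::plot(tr@times, tr@dff, type = "l",
                   main = sprintf("ROI %d trace", ev$roi),
                   xlab = "time (s)", ylab = "dF/F0")
    graphics::abline(v = (ev$peak_t - 1) / dff@meta@frameRate, lty = 2)
    graphics::par(op)
    grDevices::dev.off()
    files <- c(files, f)
  }
  labPath <- file.path(path, "labels.csv")
  utils::write.csv(ord[, c("roi", "verdict", "class_label")], labPath,
                   row.names = FALSE)
  invisible(c(files, labPath))
}

#' Re-import curated labels
#'
#' Reads a gallery `labels.csv` after editing and transfers `verdict` and
#' `class_label` onto the matching rows of the event table. Unknown class
#' labels (not in [eventClasses()] and not empty) raise an error.
#'
#' @param records Event table from [eventRecords()].
#' @param labelsCsv Path of the edited `labels.csv`.
#' @return The updated event table.
#' @export
importCuration <- function(records, labelsCsv) {
  lab <- utils::read.csv(labelsCsv, stringsAsFactors = FALSE)
  need <- c("roi", "verdict", "class_label")
  if (!all(need %in% names(lab)))
    stop("labels file must have columns: ", paste(need, collapse = ", "))
  lab$class_label[is.na(lab$class_label)] <- ""
  badClass <- setdiff(unique(lab$class_label), c("", eventClasses()))
  if (length(badClass))
    stop("unknown class labels: ", paste(badClass, collapse = ", "))
  if (any(!lab$verdict %in% c("accept", "reject")))
    stop("'verdict' must be 'accept' or 'reject'")
  j <- match(lab$roi, records$roi)
  if (anyNA(j)) stop("labels reference unknown ROI ids")
  records$verdict[j] <- lab$verdict
  records$class_label[j] <- lab$class_label
  records
}
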