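# A hand-built DffStack whose single ROI has a known trace.
traceFixture <- function() {
  arr <- array(0, c(60, 6, 6))
  # two-pixel footprint at rows 3, cols 3:4; triangular time course
  tri <- c(seq(0.1, 1, by = 0.1), seq(0.9, 0, by = -0.1))
  arr[25 + seq_along(tri) - 1, 3, 3] <- tri
  arr[25 + seq_along(tri) - 1, 3, 4] <- tri * 0.5
  dff <- new("DffStack", data = arr, validFrom = 16L,
             meta = acquisitionMeta(6, 6, 60, frameRate = 28.77))
  vox <- cbind(frame = 25:44, row = 3L, col = 3L)
  vox <- rbind(vox, cbind(frame = 25:44, row = 3L, col = 4L))
  roi <- new("Roi3D", voxels = vox, dffValues = arr[cbind(vox)],
             peak = c(34L, 3L, 3L), peakDff = 1,
             centroid = c(34, 3, 3.2))
  list(dff = dff, roi = roi)
}

test_that("extracted traces average the union footprint with context", {
  fx <- traceFixture()
  tr <- extractTrace(fx$roi, fx$dff, contextFrames = 5L)
  expect_equal(tr@window, c(20L, 49L))
  expect_equal(nrow(tr@footprint), 2L)
  # mean of the two pixels: (1 + 0.5)/2 at the peak frame
  expect_equal(tr@dff[tr@frames == 34], 0.75)
  expect_equal(tr@dff[tr@frames == 20], 0)
  # enlarging the context never changes shared frames
  tr2 <- extractTrace(fx$roi, fx$dff, contextFrames = 9L)
  expect_equal(tr2@dff[match(tr@frames, tr2@frames)], tr@dff)
})

test_that("kinetics on a symmetric triangle match the analytic values", {
  fr <- 28.77
  tri <- c(rep(0, 20), seq(0.1, 1, by = 0.1), seq(0.9, 0, by = -0.1))
  k <- computeKinetics(tri, frameRate = fr)
  expect_equal(k$baseline, 0)
  expect_equal(k$amplitude, 1)
  expect_equal(k$fwhm_s, 10 / fr, tolerance = 1e-9)     # 0.34757...
  expect_equal(k$rise_time_s, 8 / fr, tolerance = 1e-9) # 0.27807...
  expect_equal(k$decay_time_s, 8 / fr, tolerance = 1e-9)
})

test_that("a single-frame spike has FWHM of one frame period", {
  k <- computeKinetics(c(0, 0, 0, 1, 0, 0), frameRate = 28.77)
  expect_equal(k$fwhm_s, 1 / 28.77, tolerance = 1e-9)
})

test_that("time parameters are invariant to positive rescaling", {
  set.seed(12)
  y <- c(rep(0, 15), dgamma(seq(0, 6, length.out = 40), shape = 2), rep(0, 10))
  k1 <- computeKinetics(y, 28.77)
  for (c0 in c(0.01, 3, 250)) {
    k2 <- computeKinetics(y * c0, 28.77)
    expect_equal(k2$fwhm_s, k1$fwhm_s, tolerance = 1e-12)
    expect_equal(k2$rise_time_s, k1$rise_time_s, tolerance = 1e-12)
    expect_equal(k2$decay_time_s, k1$decay_time_s, tolerance = 1e-12)
    expect_equal(k2$amplitude, k1$amplitude * c0, tolerance = 1e-12)
  }
})

test_that("flanks that never cross a level yield flagged NA fields", {
  # monotone rise to a plateau at the window edge: no decay crossing
  k <- computeKinetics(c(0, 0.2, 0.5, 0.9, 1), 28.77)
  expect_true(is.na(k$decay_time_s))
  expect_true(is.na(k$fwhm_s))
  expect_false(is.na(k$rise_time_s))
})

test_that("areas use the peak-frame footprint and the 0.16 um^2 pixel", {
  fx <- traceFixture()
  expect_equal(computeArea(fx$roi, pixelSize = 0.4), 2 * 0.16)
  # 10-pixel footprint at the peak frame
  vox <- cbind(frame = 5L, row = 1:10, col = 2L)
  roi <- new("Roi3D", voxels = vox, dffValues = c(2, rep(1, 9)),
             peak = c(5L, 1L, 2L), peakDff = 2, centroid = c(5, 5.5, 2))
  expect_equal(computeArea(roi, 0.4), 1.6)
  expect_equal(computeArea(roi, 0.2), 10 * 0.04)
})

test_that("event records satisfy the integrated-amplitude identity", {
  m <- transientMovie(seed = 22L)
  cfg <- filterConfig(sigmaSpatial = 1, sigmaTemporal = 1)
  res <- detectEvents(m, cfg)
  dff <- computeDff(gaussianFilter3d(m, cfg), cfg, meta = meta(m))
  rec <- eventRecords(res, dff)
  expect_gte(nrow(rec), 1L)
  expect_equal(rec$integrated_amplitude, rec$amplitude * rec$area_um2)
  expect_true(all(rec$amplitude > 0))
  defined <- !is.na(rec$fwhm_s)
  expect_true(all(rec$fwhm_s[defined] > 0))
})

test_that("fixed-ROI manual mode reproduces the boxcar closed form", {
  arr <- array(100, c(200, 6, 6)); arr[100:110, , ] <- 120
  m <- movieStack(arr)
  rec <- fixedRoiAnalysis(m, cbind(3, 3), mode = "manual")
  # the preceding bleach fit absorbs a sliver of the boxcar
  expect_equal(rec$amplitude, 0.2, tolerance = 0.02)
  expect_lt(abs(rec$baseline), 0.01)
  expect_true(rec$peak_frame %in% 100:110)
  expect_error(fixedRoiAnalysis(movieStack(array(10, c(20, 4, 4))),
                                cbind(2, 2), mode = "manual"),
               "at least 25")
  expect_error(fixedRoiAnalysis(m, cbind(40, 2), mode = "manual"),
               "outside the image bounds")
})

test_that("assisted and manual fixed-ROI amplitudes agree on clean data", {
  # noise-free synthetic transient on a flat background
  arr <- array(1000, c(300, 8, 8))
  tmpl <- makeEventTemplate()
  for (i in seq_along(tmpl@samples))
    arr[150 + i - 1, , ] <- 1000 + 200 * tmpl@samples[i]
  m <- movieStack(round(arr))
  roi2d <- as.matrix(expand.grid(3:6, 3:6))
  a <- fixedRoiAnalysis(m, roi2d, mode = "assisted",
                        cfg = filterConfig(sigmaSpatial = 0, sigmaTemporal = 0))
  mm <- fixedRoiAnalysis(m, roi2d, mode = "manual")
  expect_lt(abs(a$amplitude - mm$amplitude) / mm$amplitude, 0.1)
  # manual (grid-snapped) FWHM within one frame period of the interpolated one
  expect_lt(abs(a$fwhm_s - mm$fwhm_s), 1 / 28.77 + 1e-12)
})

test_that("sorting is stable, descending, and a permutation", {
  rec <- data.frame(roi = 1:4, peak_dff = c(0.5, 0.9, 0.7, 0.9),
                    peak_t = c(10L, 30L, 20L, 5L),
                    n_voxels = c(4L, 4L, 4L, 4L),
                    integrated_amplitude = c(1, 2, 3, 4))
  s <- sortRois(rec, "peak_dff")
  expect_equal(s$roi, c(4L, 2L, 3L, 1L))  # ties by earlier peak frame
  expect_setequal(s$roi, rec$roi)
  sAll <- sortRois(rec, "n_voxels")
  expect_equal(sAll$roi, c(4L, 1L, 3L, 2L))  # all equal: peak_t then id
})

test_that("two-level summaries average per event, then per cell", {
  rec <- data.frame(
    roi = 1:3, cell = c("A", "A", "B"),
    amplitude = c(0.1, 0.3, 0.2), fwhm_s = c(0.3, 0.5, 0.4),
    verdict = "accept", class_label = "")
  s <- summarizeEvents(rec, durations = c(A = 60, B = 10))
  expect_equal(s$perCell$amplitude, c(0.2, 0.2))
  expect_equal(s$overall$mean[s$overall$parameter == "amplitude"], 0.2)
  expect_equal(s$perCell$frequency_hz, c(2 / 60, 1 / 10))
  # 12 events in 60 s -> 0.2 Hz
  rec12 <- data.frame(roi = 1:12, cell = "C", amplitude = 0.1,
                      verdict = "accept", class_label = "")
  s12 <- summarizeEvents(rec12, durations = c(C = 60))
  expect_equal(s12$perCell$frequency_hz, 0.2)
  # order invariance of the overall mean
  s2 <- summarizeEvents(rec[c(3, 1, 2), ], durations = c(A = 60, B = 10))
  expect_equal(s2$overall$mean, s$overall$mean)
  expect_error(summarizeEvents(rec, durations = c(A = 0, B = 10)), "positive")
})

test_that("rejected events are excluded from summaries", {
  rec <- data.frame(roi = 1:3, cell = "A", amplitude = c(1, 100, 1),
                    verdict = c("accept", "reject", "accept"),
                    class_label = "")
  s <- summarizeEvents(rec, durations = c(A = 10))
  expect_equal(s$perCell$n_events, 2L)
  expect_equal(s$perCell$amplitude, 1)
})

test_that("gallery export writes one montage per event and labels round-trip", {
  m <- transientMovie(seed = 23L)
  cfg <- filterConfig(sigmaSpatial = 1, sigmaTemporal = 1)
  res <- detectEvents(m, cfg)
  dff <- computeDff(gaussianFilter3d(m, cfg), cfg, meta = meta(m))
  rec <- eventRecords(res, dff)
  out <- withr::local_tempdir()
  files <- exportGallery(rec, res, dff, m, out)
  pngs <- list.files(out, pattern = "\\.png$")
  expect_length(pngs, nrow(rec))
  expect_true(all(file.size(file.path(out, pngs)) > 0))
  lab <- utils::read.csv(file.path(out, "labels.csv"))
  expect_equal(nrow(lab), nrow(rec))
  # curate one row and re-import: exactly that record changes
  lab$verdict[1] <- "reject"
  lab$class_label[1] <- "FastSingle"
  utils::write.csv(lab, file.path(out, "labels.csv"), row.names = FALSE)
  rec2 <- importCuration(rec, file.path(out, "labels.csv"))
  changed <- which(rec2$class_label != rec$class_label)
  expect_equal(rec2$roi[changed], lab$roi[1])
  expect_equal(rec2$class_label[changed], "FastSingle")
  lab$class_label[1] <- "NotAClass"
  utils::write.csv(lab, file.path(out, "labels.csv"), row.names = FALSE)
  expect_error(importCuration(rec, file.path(out, "labels.csv")),
               "unknown class labels")
})
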