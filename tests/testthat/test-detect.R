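test_that("frame threshold matches hand-computed median + k*IQR", {
  # {1..11}: median 6, Q3 - Q1 = 8.5 - 3.5 = 5 (type-7 percentiles)
  expect_equal(frameThreshold(1:11, k = 3), 21)
  expect_equal(frameThreshold(rep(4.2, 50)), 4.2)   # constant: IQR 0
  # shift equivariance
  set.seed(7); x <- rnorm(201)
  for (c0 in c(-3, 0.5, 10))
    expect_equal(frameThreshold(x + c0), frameThreshold(x) + c0,
                 tolerance = 1e-12)
})

test_that("binarize marks strict exceedances frame by frame", {
  arr <- array(100, c(30, 6, 6))
  arr[25, 3, 4] <- 500   # one outlier on a uniform background
  d <- computeDff(arr, filterConfig(sigmaSpatial = 0, sigmaTemporal = 0))
  b <- binarizeDff(d, k = 3)
  expect_equal(which(b$binary), which(dffData(d) > 0 & !is.na(dffData(d)) &
                                      dffData(d) > b$thresholds[25]))
  expect_equal(sum(b$binary), 1L)
  expect_equal(which(b$binary, arr.ind = TRUE)[1, ], c(25L, 3L, 4L),
               ignore_attr = TRUE)
  expect_true(all(is.na(b$thresholds[1:15])))
  # all-zero dff -> all-false
  d0 <- computeDff(array(50, c(25, 4, 4)),
                   filterConfig(sigmaSpatial = 0, sigmaTemporal = 0))
  expect_false(any(binarizeDff(d0)$binary))
})

test_that("raising the threshold multiplier only shrinks the marked set", {
  set.seed(8)
  arr <- array(rpois(40 * 8 * 8, 100), c(40, 8, 8))
  d <- computeDff(arr, filterConfig(sigmaSpatial = 1, sigmaTemporal = 1))
  prev <- binarizeDff(d, k = 1)$binary
  for (k in c(2, 3, 5)) {
    cur <- binarizeDff(d, k = k)$binary
    expect_true(all(prev | !cur))   # cur subset of prev
    prev <- cur
  }
})

test_that("connectivity semantics: diagonal and temporal adjacency", {
  b <- array(FALSE, c(3, 5, 5))
  b[2, 2, 2] <- TRUE; b[2, 3, 3] <- TRUE     # spatial diagonal, same frame
  expect_length(labelComponents3d(b, connectivity = 26L), 1L)
  expect_length(labelComponents3d(b, connectivity = 6L), 2L)
  b2 <- array(FALSE, c(4, 4, 4))
  b2[2, 2, 2] <- TRUE; b2[3, 2, 2] <- TRUE   # same pixel, consecutive frames
  expect_length(labelComponents3d(b2, connectivity = 6L), 1L)
})

test_that("component labelling agrees with brute-force flood fill", {
  set.seed(9)
  for (rep in 1:100) {
    b <- array(runif(8 * 8 * 8) < 0.12, c(8, 8, 8))
    for (conn in c(6L, 26L)) {
      rois <- labelComponents3d(b, connectivity = conn)
      oracle <- floodFillLabels(b, connectivity = conn)
      expect_identical(roiPartitionSignature(rois, dim(b)),
                       partitionSignature(oracle),
                       label = sprintf("rep %d conn %d", rep, conn))
    }
  }
})

test_that("pre-filter ROIs conserve and partition the marked voxels", {
  set.seed(10)
  b <- array(runif(10 * 12 * 12) < 0.1, c(10, 12, 12))
  rois <- labelComponents3d(b)
  expect_equal(sum(vapply(rois, nVoxels, 0L)), sum(b))
  lin <- unlist(lapply(rois, function(r) {
    v <- r@voxels
    v[, 1L] + (v[, 2L] - 1L) * 10 + (v[, 3L] - 1L) * 120
  }))
  expect_false(anyDuplicated(lin) > 0)      # pairwise disjoint
  expect_setequal(lin, which(b))
})

test_that("ROI peaks and weighted centroids come from the dF/F0 values", {
  b <- array(FALSE, c(5, 5, 5))
  b[2, 2, 2] <- b[2, 2, 3] <- b[3, 2, 2] <- TRUE
  vals <- array(0, c(5, 5, 5))
  vals[2, 2, 2] <- 0.2; vals[2, 2, 3] <- 0.6; vals[3, 2, 2] <- 0.2
  rois <- labelComponents3d(b, vals)
  expect_length(rois, 1L)
  r <- rois[[1]]
  expect_equal(peakOf(r), c(frame = 2L, row = 2L, col = 3L))
  expect_equal(r@peakDff, 0.6)
  expect_equal(r@centroid, c(2.2, 2, 2.6), tolerance = 1e-12)
  expect_equal(tExtent(r), c(2L, 3L))
  expect_lte(nrow(unionFootprint(r)), nVoxels(r))
})

test_that("ROI filters implement the size and mask rules", {
  b <- array(FALSE, c(6, 8, 8))
  b[3, 2, 2] <- TRUE                          # single voxel: hot pixel
  b[4, 6, 6] <- b[4, 6, 7] <- TRUE            # two voxels, peak at (6,6)
  vals <- array(0, c(6, 8, 8))
  vals[3, 2, 2] <- 1; vals[4, 6, 6] <- 0.5; vals[4, 6, 7] <- 0.3
  rois <- labelComponents3d(b, vals)
  mask <- matrix(FALSE, 8, 8); mask[5:8, 5:8] <- TRUE

  out <- filterRois(rois, mask, filterConfig())
  expect_length(out$rois, 1L)
  expect_equal(out$rejected[["size"]], 1L)
  expect_equal(peakOf(out$rois[[1]])[2:3], c(row = 6L, col = 6L))

  # peak outside the mask: rejected iff useMask
  maskOff <- matrix(FALSE, 8, 8); maskOff[1, 1] <- TRUE
  keepOff <- filterRois(rois, maskOff, filterConfig(useMask = FALSE))
  expect_length(keepOff$rois, 1L)
  dropOn <- filterRois(rois, maskOff, filterConfig(useMask = TRUE))
  expect_length(dropOn$rois, 0L)
  expect_equal(dropOn$rejected[["mask"]], 1L)
})

test_that("detectEvents finds an inserted transient and is deterministic", {
  m <- transientMovie(seed = 21L)
  cfg <- filterConfig(sigmaSpatial = 1, sigmaTemporal = 1)
  res <- detectEvents(m, cfg)
  expect_gte(length(rois(res)), 1L)
  peaks <- t(vapply(rois(res), peakOf, integer(3)))
  hit <- abs(peaks[, 1] - 40) <= 2 & abs(peaks[, 2] - 12) <= 1 &
    abs(peaks[, 3] - 12) <= 1
  expect_true(any(hit))
  # pure function: identical result on rerun
  res2 <- detectEvents(m, cfg)
  expect_equal(roiTable(res), roiTable(res2))
  expect_equal(thresholds(res), thresholds(res2))
  # constant movie: no events (mask degenerates with a warning)
  suppressWarnings(resC <- detectEvents(constantMovie(), cfg))
  expect_length(rois(resC), 0L)
})
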