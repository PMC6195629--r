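fakeTruth <- function(events, nFrames = 600L) {
  new("GroundTruth", events = events, snr = 1, seed = 1L,
      params = list(usableFrames = c(16L, nFrames - 29L), nFrames = nFrames))
}

detTable <- function(...) {
  df <- as.data.frame(rbind(...))
  names(df) <- c("peak_t", "peak_y", "peak_x")
  df$roi <- seq_len(nrow(df))
  df
}

test_that("matching applies the 1 px / 10 frame tolerance exactly", {
  truth <- fakeTruth(data.frame(event_id = 1L, frame = 100L, row = 20L,
                                col = 20L))
  # exact hit
  expect_equal(tpr(matchDetections(truth, detTable(c(100, 20, 20)))), 1)
  # offset 2 px: unmatched; offset 1 px and 5 frames: matched
  expect_equal(tpr(matchDetections(truth, detTable(c(100, 22, 20)))), 0)
  expect_equal(tpr(matchDetections(truth, detTable(c(105, 21, 20)))), 1)
  # offset 11 frames: unmatched
  expect_equal(tpr(matchDetections(truth, detTable(c(111, 20, 20)))), 0)
  # no detections at all
  empty <- detTable(c(1, 1, 1))[0, ]
  expect_equal(tpr(matchDetections(truth, empty)), 0)
})

test_that("matching is one-to-one, greedy by distance, and conservative", {
  truth <- fakeTruth(data.frame(event_id = 1:2, frame = c(100L, 100L),
                                row = c(20L, 23L), col = c(20L, 20L)))
  # one detection between two truth events: exactly one pair, the nearer one
  mr <- matchDetections(truth, detTable(c(100, 21, 20)), maxDxy = 3)
  expect_equal(mr@nMatched, 1L)
  expect_equal(mr@pairs$truth_id, 1L)
  # two detections, two truths: both match despite cross-compatibility
  mr2 <- matchDetections(truth, detTable(c(100, 20, 20), c(100, 23, 20)),
                         maxDxy = 3)
  expect_equal(mr2@nMatched, 2L)
  expect_lte(mr2@nMatched, min(mr2@nTruth, mr2@nDetected))
})

test_that("widening tolerances never decreases the TPR", {
  set.seed(71)
  truth <- fakeTruth(data.frame(event_id = 1:30,
                                frame = sample(50:500, 30),
                                row = sample(5:40, 30, TRUE),
                                col = sample(5:40, 30, TRUE)))
  det <- detTable(cbind(sample(50:500, 25), sample(5:40, 25, TRUE),
                        sample(5:40, 25, TRUE)))
  prev <- -1
  for (tol in list(c(0, 2), c(1, 5), c(1, 10), c(2, 15), c(4, 30))) {
    cur <- tpr(matchDetections(truth, det, maxDxy = tol[1], maxDt = tol[2]))
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("truth events outside the usable range leave the denominator", {
  truth <- fakeTruth(data.frame(event_id = 1:3, frame = c(5L, 100L, 590L),
                                row = 20L, col = 20L))
  mr <- matchDetections(truth, detTable(c(100, 20, 20)))
  expect_equal(mr@nExcluded, 2L)   # frames 5 and 590 are undetectable
  expect_equal(mr@nTruth, 1L)
  expect_equal(tpr(mr), 1)
})

test_that("sigmoid fit exactly recovers noise-free logistic data", {
  a <- 0.9; x0 <- 2; b <- 0.4
  df <- data.frame(snr = seq(0, 7, by = 0.25))
  df$tpr <- a / (1 + exp(-(df$snr - x0) / b))
  fit <- fitSigmoid(df)
  expect_lt(abs(fit@a - a) / a, 1e-6)
  expect_lt(abs(fit@x0 - x0) / x0, 1e-6)
  expect_lt(abs(fit@b - b) / b, 1e-6)
  # analytic identity of the logistic
  expect_equal(snr99(fit) - fit@x0, fit@b * log(99), tolerance = 1e-12)
  expect_equal(tprAtHalf(fit), fit@a / 2)
  expect_error(fitSigmoid(df[1:3, ]), "at least 4")
})

test_that("a small SNR sweep is reproducible and behaves sensibly", {
  syn <- syntheticNoiseModel(height = 40L, width = 40L)
  tmpl <- makeEventTemplate()
  grid <- c(0, 3, 8)
  run <- function() runSnrSweep(
    snrGrid = grid, noise = syn$noise, mask = syn$mask, template = tmpl,
    nEvents = 10L, nFrames = 140L, replicates = 2L, baseSeed = 5L)
  c1 <- run(); c2 <- run()
  expect_identical(c1@points, c2@points)
  expect_identical(c1@replicates, c2@replicates)
  expect_true(all(diff(c1@points$snr) > 0))
  # chance-level matches only at SNR 0, strong detection at SNR 8
  expect_lt(c1@points$tpr[1], 0.25)
  expect_gt(c1@points$tpr[3], c1@points$tpr[1])
})

test_that("performance reports round-trip the fit and write the bundle", {
  df <- data.frame(snr = rep(seq(0, 6, by = 0.5), each = 2))
  set.seed(81)
  df$tpr <- pmin(pmax(
    0.85 / (1 + exp(-(df$snr - 1.9) / 0.45)) + rnorm(nrow(df), 0, 0.02),
    0), 1)
  df$replicate <- rep(1:2, 13); df$seed <- seq_len(nrow(df))
  fit <- fitSigmoid(df)
  curve <- new("BenchmarkCurve",
               points = do.call(rbind, lapply(split(df, df$snr), function(g)
                 data.frame(snr = g$snr[1], tpr = mean(g$tpr), n = nrow(g)))),
               replicates = df, config = list(snrGrid = unique(df$snr)))
  out <- withr::local_tempdir()
  performanceReport(fit, curve, out)
  expect_true(all(file.exists(file.path(
    out, c("curve.csv", "replicates.csv", "fit.json", "performance.png")))))
  expect_gt(file.size(file.path(out, "performance.png")), 0)
  expect_equal(nrow(utils::read.csv(file.path(out, "curve.csv"))),
               length(unique(df$snr)))
  back <- readSigmoidFit(file.path(out, "fit.json"))
  expect_equal(back@a, fit@a)
  expect_equal(back@x0, fit@x0)
  expect_equal(back@b, fit@b)
  expect_equal(snr99(back), snr99(fit))
})
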