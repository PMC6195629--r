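# Shared fixtures and independent oracles, built in code at test time.

# A flat movie with Poisson-free constant background (useful for exact
# arithmetic checks).
constantMovie <- function(value = 100L, nFrames = 40L, side = 8L) {
  movieStack(array(as.numeric(value), c(nFrames, side, side)))
}

# A noisy movie with one inserted bright transient blob, guaranteed to be
# far above any plausible threshold.
transientMovie <- function(seed = 1L, nFrames = 80L, side = 24L,
                           peakFrame = 40L, peakY = 12L, peakX = 12L,
                           amplitude = 3000) {
  set.seed(seed)
  arr <- array(rpois(nFrames * side * side, 400), c(nFrames, side, side))
  # a bright static square so the inclusion mask contains the event site
  arr[, 6:18, 6:18] <- arr[, 6:18, 6:18] + 300
  for (dt in -2:2) for (dy in -2:2) for (dx in -2:2) {
    w <- exp(-(dt^2 + dy^2 + dx^2) / 4)
    arr[peakFrame + dt, peakY + dy, peakX + dx] <-
      arr[peakFrame + dt, peakY + dy, peakX + dx] + amplitude * w
  }
  movieStack(array(pmin(round(arr), 65535), dim(arr)))
}

# Independent brute-force flood fill (BFS over an explicit neighbour
# search); deliberately shares no code with labelComponents3d().
floodFillLabels <- function(binary, connectivity = 26L) {
  d <- dim(binary)
  offs <- expand.grid(dt = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dt == 0 & offs$dy == 0 & offs$dx == 0), ]
  nnz <- abs(offs$dt) + abs(offs$dy) + abs(offs$dx)
  offs <- switch(as.character(connectivity),
                 "6" = offs[nnz == 1, ], "18" = offs[nnz <= 2, ], offs)
  labels <- array(0L, d)
  cur <- 0L
  todo <- which(binary, arr.ind = TRUE)
  for (k in seq_len(nrow(todo))) {
    p <- todo[k, ]
    if (labels[p[1L], p[2L], p[3L]] != 0L || !binary[p[1L], p[2L], p[3L]])
      next
    cur <- cur + 1L
    queue <- list(p)
    labels[p[1L], p[2L], p[3L]] <- cur
    while (length(queue)) {
      q <- queue[[1L]]; queue <- queue[-1L]
      for (o in seq_len(nrow(offs))) {
        nb <- q + c(offs$dt[o], offs$dy[o], offs$dx[o])
        if (any(nb < 1L) || any(nb > d)) next
        if (binary[nb[1L], nb[2L], nb[3L]] &&
            labels[nb[1L], nb[2L], nb[3L]] == 0L) {
          labels[nb[1L], nb[2L], nb[3L]] <- cur
          queue[[length(queue) + 1L]] <- nb
        }
      }
    }
  }
  labels
}

# Canonical partition signature: sorted list of sorted voxel-index sets,
# for comparing two labelings up to label permutation.
partitionSignature <- function(labels) {
  idx <- which(labels != 0L)
  if (!length(idx)) return(character())
  sets <- split(idx, labels[idx])
  sort(vapply(sets, function(s) paste(sort(s), collapse = ","), ""))
}

roiPartitionSignature <- function(rois, dims) {
  sets <- vapply(rois, function(r) {
    v <- r@voxels
    lin <- v[, 1L] + (v[, 2L] - 1L) * dims[1L] +
      (v[, 3L] - 1L) * dims[1L] * dims[2L]
    paste(sort(lin), collapse = ",")
  }, "")
  sort(sets)
}

# Small simulation bundle shared by several tests.
miniSimulation <- function(snr = 6, seed = 11L, side = 48L, nFrames = 160L,
                           nEvents = 8L) {
  syn <- syntheticNoiseModel(height = side, width = side)
  tmpl <- makeEventTemplate()
  sim <- suppressMessages(simulateMovie(
    syn$noise, syn$mask, tmpl, snr = snr, nEvents = nEvents,
    nFrames = nFrames, seed = seed))
  c(sim, list(noise = syn$noise, mask = syn$mask, template = tmpl))
}
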