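#' Robust per-frame threshold
#'
#' The detection threshold of one frame is `median(values) + k * IQR(values)`
#' with the interquartile range `IQR = Q75 - Q25` (linear-interpolation
#' percentiles, R quantile type 7). The median and IQR are insensitive to
#' the sparse supra-threshold transients themselves, so the threshold
#' tracks the noise floor rather than the signal.
#'
#' @param values Numeric vector of one frame's dF/F0 values.
#' @param k IQR multiplier (default 3).
#' @return The threshold, a single number.
#' @examples
#' frameThreshold(1:11, k = 3)   # median 6 + 3 * (8.5 - 3.5) = 21
#' @export
frameThreshold <- function(values, k = 3) {
  stopifnot(length(values) > 0L, k > 0)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  q[2L] + k * (q[3L] - q[1L])
}

#' Threshold a dF/F0 stack frame by frame
#'
#' A voxel is marked when its dF/F0 strictly exceeds its frame's threshold
#' (computed over all pixels of that frame). Frames before the baseline
#' warm-up are all-`FALSE` and their threshold is `NA`.
#'
#' @param dff A [DffStack-class].
#' @param k IQR multiplier.
#' @return A list with `binary` (logical 3D array) and `thresholds`
#'   (numeric per-frame vector, `NA` on invalid frames).
#' @seealso [frameThreshold()], [labelComponents3d()]
#' @export
binarizeDff <- function(dff, k = 3) {
  stopifnot(is(dff, "DffStack"))
  d <- dim(dff@data)
  M <- asFramePixelMatrix(dff@data)
  thr <- rep(NA_real_, d[1L])
  tt <- dff@validFrom:d[1L]
  q <- apply(M[tt, , drop = FALSE], 1L, stats::quantile,
             probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  thr[tt] <- q[2L, ] + k * (q[3L, ] - q[1L, ])
  bin <- matrix(FALSE, d[1L], ncol(M))
  bin[tt, ] <- M[tt, , drop = FALSE] > thr[tt]
  list(binary = array(bin, dim = d), thresholds = thr)
}

# Half-neighbourhood offsets (lexicographically positive) for a given
# 3D connectivity; the mirrored half is implied by undirected adjacency.
halfOffsets <- function(connectivity) {
  g <- expand.grid(dt = -1:1, dy = -1:1, dx = -1:1)
  g <- g[g$dt != 0 | g$dy != 0 | g$dx != 0, ]
  nnz <- abs(g$dt) + abs(g$dy) + abs(g$dx)
  g <- switch(as.character(connectivity),
    "6" = g[nnz == 1L, ],
    "18" = g[nnz <= 2L, ],
    "26" = g,
    stop("connectivity must be 6, 18 or 26"))
  keep <- g$dt > 0 | (g$dt == 0 & (g$dy > 0 | (g$dy == 0 & g$dx > 0)))
  as.matrix(g[keep, c("dt", "dy", "dx")])
}

#' Group supra-threshold voxels into 3D ROIs
#'
#' Partitions the marked voxels into maximal connected components in
#' `(t, y, x)` space. The default 26-connectivity treats all voxels
#' sharing a face, edge or corner as neighbours, so pixels adjacent in
#' space *or* in time join the same ROI. Components are realized as an
#' undirected voxel-adjacency graph whose connected components are found
#' with \pkg{igraph}.
#'
#' @param binary Logical 3D array `(t, y, x)`.
#' @param dff Optional [DffStack-class] (or bare 3D array) supplying the
#'   dF/F0 values for peaks and weighted centroids; without it, voxel
#'   values default to 1 and the peak is the first voxel in array order.
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (full).
#' @return List of [Roi3D-class], ordered by first voxel in array order.
#' @seealso [filterRois()], [detectEvents()]
#' @export
labelComponents3d <- function(binary, dff = NULL, connectivity = 26L) {
  stopifnot(is.logical(binary), length(dim(binary)) == 3L)
  d <- dim(binary)
  lin <- which(binary)
  n <- length(lin)
  if (n == 0L) return(list())
  coords <- which(binary, arr.ind = TRUE)          # columns: dim1, dim2, dim3
  vals <- if (is.null(dff)) rep(1, n) else {
    arr <- if (is(dff, "DffStack")) dff@data else dff
    arr[lin]
  }
  offs <- halfOffsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(nrow(offs))) {
    nt <- coords[, 1L] + offs[i, 1L]
    ny <- coords[, 2L] + offs[i, 2L]
    nx <- coords[, 3L] + offs[i, 3L]
    ok <- nt >= 1L & nt <= d[1L] & ny >= 1L & ny <= d[2L] &
          nx >= 1L & nx <= d[3L]
    if (!any(ok)) next
    nlin <- nt[ok] + (ny[ok] - 1) * d[1L] + (nx[ok] - 1) * d[1L] * d[2L]
    j <- match(nlin, lin)
    hit <- !is.na(j)
    if (any(hit)) {
      from <- c(from, which(ok)[hit])
      to <- c(to, j[hit])
    }
  }
  memb <- if (length(from)) {
    g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
    igraph::components(g)$membership
  } else seq_len(n)
  comp <- split(seq_len(n), memb)
  # deterministic ROI order: by smallest linear voxel index
  comp <- comp[order(vapply(comp, function(i) min(lin[i]), 0))]
  lapply(comp, function(i) {
    v <- coords[i, , drop = FALSE]
    colnames(v) <- c("frame", "row", "col")
    storage.mode(v) <- "integer"
    w <- vals[i]
    ip <- which.max(w)
    cen <- if (sum(w) > 0) colSums(v * w) / sum(w) else colMeans(v)
    new("Roi3D", voxels = v, dffValues = w,
        peak = v[ip, ], peakDff = w[ip], centroid = unname(cen))
  })
}

#' Apply ROI inclusion filters
#'
#' Two filters: (1) ROIs smaller than `minVoxels` voxels are removed —
#' with the default of 2 this kills single-voxel "hot pixel" events, which
#' are inconsistent with the optical point-spread function; (2) when
#' `useMask` is on, ROIs lying outside the inclusion mask are removed
#' (membership judged by the peak pixel in `"peak"` mode, or by any voxel
#' in `"any"` mode).
#'
#' @param rois List of [Roi3D-class] from [labelComponents3d()].
#' @param mask Logical `(row, column)` inclusion mask, or `NULL`.
#' @param cfg A [FilterConfig-class].
#' @return List with `rois` (the survivors, order preserved) and
#'   `rejected` (named integer tally: `size`, `mask`).
#' @export
filterRois <- function(rois, mask = NULL, cfg = filterConfig()) {
  tally <- c(size = 0L, mask = 0L)
  keep <- logical(length(rois))
  for (i in seq_along(rois)) {
    roi <- rois[[i]]
    if (nVoxels(roi) < cfg@minVoxels) {
      tally["size"] <- tally["size"] + 1L
      next
    }
    if (cfg@useMask && !is.null(mask)) {
      inside <- if (cfg@maskMode == "peak") {
        mask[roi@peak[2L], roi@peak[3L]]
      } else {
        any(mask[roi@voxels[, 2:3, drop = FALSE]])
      }
      if (!inside) {
        tally["mask"] <- tally["mask"] + 1L
        next
      }
    }
    keep[i] <- TRUE
  }
  list(rois = rois[keep], rejected = tally)
}

#' Run the full detection pipeline
#'
#' Composition of the pipeline stages: 3D Gaussian filter, moving-baseline
#' dF/F0, inclusion mask (computed on the *raw* stack), per-frame
#' median + k x IQR thresholding, 3D connected-component grouping, and ROI
#' filters. The result is a pure function of `(stack, cfg)`: rerunning on
#' the same input yields identical ROIs.
#'
#' @param stack A [MovieStack-class].
#' @param cfg A [FilterConfig-class].
#' @param provenance Optional list recorded in the result (e.g. the input
#'   path).
#' @return A [DetectionResult-class].
#' @examples
#' set.seed(1)
#' arr <- array(rpois(40 * 16 * 16, 100), c(40, 16, 16))
#' res <- detectEvents(movieStack(arr),
#'                     filterConfig(sigmaSpatial = 1, sigmaTemporal = 1,
#'                                  useMask = FALSE))
#' res
#' @export
detectEvents <- function(stack, cfg = filterConfig(), provenance = list()) {
  stopifnot(is(stack, "MovieStack"))
  filtered <- gaussianFilter3d(stack, cfg)
  dff <- computeDff(filtered, cfg, meta = stack@meta)
  mask <- computeInclusionMask(stack)
  bin <- binarizeDff(dff, k = cfg@thresholdK)
  rois <- labelComponents3d(bin$binary, dff, connectivity = cfg@connectivity)
  filt <- filterRois(rois, mask, cfg)
  provenance$package_version <- as.character(utils::packageVersion("SCTdetect"))
  new("DetectionResult", rois = filt$rois, thresholds = bin$thresholds,
      mask = mask, config = cfg, rejected = filt$rejected,
      validFrom = dff@validFrom, provenance = provenance)
}

#' Tabulate detected ROIs
#'
#' One row per accepted ROI with its peak coordinates (1-based), peak
#' dF/F0, size, temporal extent, weighted centroid and areas. `area_um2`
#' is the peak-frame footprint area; `union_area_um2` the union-footprint
#' area (always >= the peak-frame area).
#'
#' @param result A [DetectionResult-class].
#' @param pixelSize Pixel side length in micrometres.
#' @return A `data.frame`, one row per ROI.
#' @export
roiTable <- function(result, pixelSize = 0.4) {
  rois <- result@rois
  if (!length(rois)) {
    return(data.frame(
      roi = integer(), peak_t = integer(), peak_y = integer(),
      peak_x = integer(), peak_dff = numeric(), n_voxels = integer(),
      t_start = integer(), t_end = integer(), centroid_t = numeric(),
      centroid_y = numeric(), centroid_x = numeric(),
      area_px = integer(), area_um2 = numeric(),
      union_area_px = integer(), union_area_um2 = numeric()))
  }
  px2 <- pixelSize^2
  rows <- lapply(seq_along(rois), function(i) {
    r <- rois[[i]]
    te <- tExtent(r)
    pk <- unname(r@peak)
    peakFp <- sum(r@voxels[, 1L] == pk[1L])
    uniFp <- nrow(unionFootprint(r))
    data.frame(
      roi = i, peak_t = pk[1L], peak_y = pk[2L], peak_x = pk[3L],
      peak_dff = r@peakDff, n_voxels = nVoxels(r),
      t_start = te[1L], t_end = te[2L],
      centroid_t = r@centroid[1L], centroid_y = r@centroid[2L],
      centroid_x = r@centroid[3L],
      area_px = peakFp, area_um2 = peakFp * px2,
      union_area_px = uniFp, union_area_um2 = uniFp * px2)
  })
  do.call(rbind, rows)
}
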