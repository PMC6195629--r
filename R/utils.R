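# Separable Gaussian convolution with replicate-edge padding.
# Kernels are truncated at 4 sigma; with a normalized kernel the truncation
# discards < 1e-4 of the mass.

gaussianKernel1d <- function(sigma, truncate = 4) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  x <- seq.int(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Correlate the columns of a matrix with a kernel via one sparse
# band-matrix product (Matrix package). "valid" returns only the
# nrow(m) - L + 1 fully covered rows (out[i, ] = sum_j k[j] *
# m[i + j - 1, ]); "replicate" returns nrow(m) rows with a centered
# kernel and out-of-range taps folded onto the edge rows, which is
# exactly replicate-edge padding without materializing the pad.
bandConvolve <- function(m, k, mode = c("valid", "replicate")) {
  mode <- match.arg(mode)
  L <- length(k)
  n0 <- nrow(m)
  if (mode == "valid") {
    n <- n0 - L + 1L
    ii <- rep.int(seq_len(n), rep.int(L, n))
    jj <- ii + rep.int(0:(L - 1L), n)
  } else {
    stopifnot(L %% 2L == 1L)
    r <- (L - 1L) %/% 2L
    n <- n0
    ii <- rep.int(seq_len(n), rep.int(L, n))
    jj <- pmin.int(pmax.int(ii + rep.int(-r:r, n), 1L), n0)
  }
  B <- Matrix::sparseMatrix(i = ii, j = jj, x = rep.int(k, n),
                            dims = c(n, n0))   # duplicated (i,j) taps sum
  as.matrix(B %*% m)
}

# Convolve a 3D array along one axis with a centered odd-length kernel,
# replicating the edge samples; the target axis is rotated into dimension 1
# first.
convolveAxis3d <- function(arr, kernel, axis) {
  L <- length(kernel)
  if (L == 1L) return(arr)
  stopifnot(L %% 2L == 1L)
  r <- (L - 1L) %/% 2L
  d0 <- dim(arr)
  if (r >= d0[axis])
    warning(sprintf(
      "Gaussian kernel half-width (%d) meets or exceeds the array extent (%d) along axis %d; replicate padding dominates",
      r, d0[axis], axis))
  if (axis == 1L) {
    d <- dim(arr)
    dim(arr) <- c(d[1L], d[2L] * d[3L])
    out <- bandConvolve(arr, kernel, mode = "replicate")
    dim(out) <- d
    return(out)
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  dim(a) <- c(d[1L], d[2L] * d[3L])
  out <- bandConvolve(a, kernel, mode = "replicate")
  dim(out) <- d
  aperm(out, order(perm))
}

# 2D Gaussian smoothing of a matrix (rows then columns), replicate padding.
# normalize = "sum" preserves total mass (standard filtering); "peak" uses a
# centre-weight-1 kernel so an isolated unit impulse keeps peak value 1
# (used to shape simulated events whose amplitude is defined at the peak).
smooth2d <- function(mat, sigma, truncate = 4, normalize = c("sum", "peak")) {
  normalize <- match.arg(normalize)
  k <- gaussianKernel1d(sigma, truncate)
  if (normalize == "peak") k <- k / max(k)
  if (length(k) == 1L) return(mat)
  t(bandConvolve(t(bandConvolve(mat, k, mode = "replicate")),
                 k, mode = "replicate"))
}

# Linear crossing time between samples i and i+1 of y at level L.
# Assumes y[i], y[i+1] straddle L; returns a fractional index.
interpCrossing <- function(y, i, level) {
  dy <- y[i + 1L] - y[i]
  if (dy == 0) return(i + 0.5)
  i + (level - y[i]) / dy
}

# Frames x pixels view of a (t, y, x) array.
asFramePixelMatrix <- function(arr) {
  d <- dim(arr)
  dim(arr) <- c(d[1L], d[2L] * d[3L])
  arr
}
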