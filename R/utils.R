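#' @keywords internal
"_PACKAGE"

GOLDEN <- (1 + sqrt(5)) / 2

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Analytic signal via FFT
#'
#' Returns `x + i H(x)` where `H` is the Hilbert transform, computed by
#' zeroing negative frequencies of the FFT. The mean of `x` is carried on the
#' real part only (the Hilbert transform of a constant is zero).
#'
#' @param x numeric vector, uniformly sampled.
#' @return complex vector the same length as `x`.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stopf("analytic_signal needs at least 2 samples")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Gaussian kernel sampled on integer offsets
#' @keywords internal
gauss_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  if (sigma <= 0) return(1)
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k / sum(k)
}

# 1D convolution along the first margin of a matrix (columns are independent
# signals), zero-padded, output same length.
conv_cols <- function(m, kernel) {
  nk <- length(kernel)
  if (nk == 1L) return(m * kernel)
  n <- nrow(m)
  pad <- (nk - 1L) %/% 2L
  mp <- rbind(matrix(0, pad, ncol(m)), m, matrix(0, nk - 1L - pad, ncol(m)))
  out <- matrix(0, n, ncol(m))
  for (j in seq_len(nk)) {
    out <- out + kernel[j] * mp[(nk - j) + seq_len(n), , drop = FALSE]
  }
  out
}

#' Separable Gaussian smoothing of an n-dimensional array
#'
#' Applies a normalized 1D Gaussian along each requested dimension in turn
#' (zero padding). Kernels sum to one, so total mass is conserved away from
#' the array boundary.
#'
#' @param a numeric array.
#' @param sigma numeric vector of standard deviations, in voxels, one per
#'   dimension (0 skips a dimension).
#' @return array of the same shape.
#' @keywords internal
gauss_smooth_nd <- function(a, sigma) {
  d <- dim(a)
  if (is.null(d)) d <- length(a)
  nd <- length(d)
  sigma <- rep_len(sigma, nd)
  for (ax in seq_len(nd)) {
    if (sigma[ax] <= 0 || d[ax] == 1L) next
    k <- gauss_kernel(sigma[ax])
    perm <- c(ax, setdiff(seq_len(nd), ax))
    ap <- aperm(array(a, d), perm)
    m <- matrix(ap, nrow = d[ax])
    m <- conv_cols(m, k)
    ap <- array(m, d[perm])
    a <- aperm(ap, order(perm))
  }
  array(a, d)
}

#' Trilinear interpolation into a 3D array
#'
#' @param vol 3D numeric array.
#' @param origin coordinates (length 3) of the lower corner of the grid
#'   (voxel (1,1,1) spans `origin` to `origin + spacing`), matching the
#'   histogram geometry convention used throughout.
#' @param spacing voxel edge lengths (length 3).
#' @param pts n x 3 matrix of query points.
#' @param outside value returned outside the grid (default `NA`).
#' @return numeric vector of length `nrow(pts)`.
#' @keywords internal
interp_trilinear <- function(vol, origin, spacing, pts, outside = NA_real_) {
  d <- dim(vol)
  gx <- (pts[, 1L] - origin[1L]) / spacing[1L] - 0.5
  gy <- (pts[, 2L] - origin[2L]) / spacing[2L] - 0.5
  gz <- (pts[, 3L] - origin[3L]) / spacing[3L] - 0.5
  # in-domain up to half a voxel beyond the outer voxel centers (clamped)
  ok <- gx >= -0.5 & gx <= d[1L] - 0.5 & gy >= -0.5 & gy <= d[2L] - 0.5 &
    gz >= -0.5 & gz <= d[3L] - 0.5
  ok[is.na(ok)] <- FALSE
  out <- rep(outside, nrow(pts))
  if (!any(ok)) return(out)
  gx <- pmin(pmax(gx[ok], 0), d[1L] - 1); gy <- pmin(pmax(gy[ok], 0), d[2L] - 1)
  gz <- pmin(pmax(gz[ok], 0), d[3L] - 1)
  i0 <- pmin(floor(gx), max(d[1L] - 2L, 0L))
  j0 <- pmin(floor(gy), max(d[2L] - 2L, 0L))
  k0 <- pmin(floor(gz), max(d[3L] - 2L, 0L))
  fx <- gx - i0; fy <- gy - j0; fz <- gz - k0
  idx <- function(di, dj, dk) {
    1L + (i0 + di) + d[1L] * ((j0 + dj) + d[2L] * (k0 + dk))
  }
  v <- vol[idx(0L, 0L, 0L)] * (1 - fx) * (1 - fy) * (1 - fz) +
    vol[idx(1L, 0L, 0L)] * fx * (1 - fy) * (1 - fz) +
    vol[idx(0L, 1L, 0L)] * (1 - fx) * fy * (1 - fz) +
    vol[idx(1L, 1L, 0L)] * fx * fy * (1 - fz) +
    vol[idx(0L, 0L, 1L)] * (1 - fx) * (1 - fy) * fz +
    vol[idx(1L, 0L, 1L)] * fx * (1 - fy) * fz +
    vol[idx(0L, 1L, 1L)] * (1 - fx) * fy * fz +
    vol[idx(1L, 1L, 1L)] * fx * fy * fz
  out[ok] <- v
  out
}

# Weighted n-dimensional histogram on a regular grid. Returns an array of
# summed weights; points outside the grid are dropped (count returned in
# attribute "n_dropped"). Bins are half-open [lo, hi).
hist_nd <- function(pts, w, origin, spacing, dims) {
  nd <- length(dims)
  idx <- rep(0, nrow(pts))
  mult <- 1L
  ok <- rep(TRUE, nrow(pts))
  for (ax in seq_len(nd)) {
    b <- floor((pts[, ax] - origin[ax]) / spacing[ax])
    ok <- ok & !is.na(b) & b >= 0 & b < dims[ax]
    b[is.na(b) | !ok] <- 0
    idx <- idx + b * mult
    mult <- mult * dims[ax]
  }
  ok[is.na(ok)] <- FALSE
  a <- numeric(prod(dims))
  if (any(ok)) {
    s <- rowsum(w[ok], idx[ok] + 1)
    a[as.integer(rownames(s))] <- s[, 1L]
  }
  out <- array(a, dims)
  attr(out, "n_dropped") <- sum(!ok)
  out
}

# Deterministic 32-bit-ish hash of an R object (for run logs).
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  v <- as.integer(raw)
  h <- 5381
  for (chunk in split(v, ceiling(seq_along(v) / 4096))) {
    h <- (h * 33 + sum(chunk * seq_along(chunk))) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

# Derive a reproducible sub-seed (< 2^31) from a base seed and a stage name.
substream_seed <- function(seed, stage) {
  u <- utf8ToInt(stage)
  as.integer((seed + sum(u * seq_along(u)) * 10007) %% 2147483629)
}
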