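#' Iteratively clipped baseline
#'
#' Repeatedly computes the mean and standard deviation, discards values
#' more than one standard deviation above the mean, and iterates until
#' nothing is discarded (or 3 or fewer values remain); the baseline is the
#' final mean. One-sided clipping makes the baseline insensitive to
#' transients above the resting level.
#'
#' @param series numeric vector (>= 3 values; NAs dropped).
#' @return baseline value.
#' @export
baseline_clip <- function(series) {
  x <- series[is.finite(series)]
  if (length(x) < 3L) stopf("baseline_clip: need at least 3 finite values")
  repeat {
    m <- mean(x)
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(m)
    keep <- x <= m + s
    if (all(keep) || sum(keep) <= 3L) return(mean(x[keep]))
    x <- x[keep]
  }
}

#' Ratiometric VOI traces from a rate movie
#'
#' For each spherical volume of interest, sums adjusted counts and dwell
#' over the VOI per time bin and channel; the ratio is the green rate over
#' the red rate, normalized by the iteratively clipped baseline of the
#' ratio trace.
#'
#' @param movie an [assemble_movie()] result (smoothing optional).
#' @param vois data frame with `x_um`, `y_um`, `z_um`, `r_um` (sphere
#'   centers and radii, template coordinates) and optionally `name`.
#' @param normalize `"baseline"` (clipped baseline), or `"none"`.
#' @return data frame of class `ratio_trace`: `voi`, `t_s` (bin centers),
#'   `green_cps`, `red_cps`, `ratio`, `ratio_norm` (NA where a bin has no
#'   dwell).
#' @export
voi_ratio <- function(movie, vois, normalize = c("baseline", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(movie, "rate_movie"))
  d <- movie$dims
  xc <- movie$origin[1] + (seq_len(d[1]) - 0.5) * movie$spacing[1]
  yc <- movie$origin[2] + (seq_len(d[2]) - 0.5) * movie$spacing[2]
  zc <- movie$origin[3] + (seq_len(d[3]) - 0.5) * movie$spacing[3]
  nt <- length(movie$t_edges) - 1L
  tc <- (movie$t_edges[-1] + movie$t_edges[-(nt + 1)]) / 2
  out <- list()
  for (i in seq_len(nrow(vois))) {
    m <- outer(outer((xc - vois$x_um[i])^2, (yc - vois$y_um[i])^2, "+"),
               (zc - vois$z_um[i])^2, "+") <= vois$r_um[i]^2
    if (!any(m)) stopf("voi_ratio: VOI %d contains no voxels", i)
    sel <- which(m)
    nvox <- prod(d)
    g <- r <- dw <- numeric(nt)
    for (tbin in seq_len(nt)) {
      off <- (tbin - 1L) * nvox
      g[tbin] <- sum(movie$green$counts[off + sel])
      r[tbin] <- sum(movie$red$counts[off + sel])
      dw[tbin] <- sum(movie$dwell[off + sel])
    }
    ok <- dw > 0
    green_cps <- ifelse(ok, g / dw, NA_real_)
    red_cps <- ifelse(ok, r / dw, NA_real_)
    ratio <- ifelse(ok & red_cps > 0, green_cps / red_cps, NA_real_)
    rn <- if (normalize == "baseline") {
      b <- baseline_clip(ratio)
      ratio / b
    } else ratio
    out[[i]] <- data.frame(
      voi = if ("name" %in% names(vois)) vois$name[i] else paste0("voi", i),
      t_s = tc, green_cps = green_cps, red_cps = red_cps, ratio = ratio,
      ratio_norm = rn)
  }
  res <- do.call(rbind, out)
  class(res) <- c("ratio_trace", "data.frame")
  res
}

#' Time-space projection of the ratiometric signal
#'
#' Sums counts and dwell over the two short axes of a box aligned with the
#' body axis, divides per channel, and normalizes the green/red ratio map
#' so its median is 1.
#'
#' @param movie an [assemble_movie()] result.
#' @param box list/vector `c(x0, x1, y0, y1, z0, z1)` (um) in template
#'   coordinates; the long axis is x.
#' @return list of class `timespace_map`: `map` (space x time, median 1),
#'   `x_um` (slice centers), `t_s` (bin centers).
#' @export
timespace_projection <- function(movie, box) {
  stopifnot(inherits(movie, "rate_movie"))
  d <- movie$dims
  xc <- movie$origin[1] + (seq_len(d[1]) - 0.5) * movie$spacing[1]
  yc <- movie$origin[2] + (seq_len(d[2]) - 0.5) * movie$spacing[2]
  zc <- movie$origin[3] + (seq_len(d[3]) - 0.5) * movie$spacing[3]
  ix <- which(xc >= box[1] & xc < box[2])
  iy <- which(yc >= box[3] & yc < box[4])
  iz <- which(zc >= box[5] & zc < box[6])
  if (!length(ix) || !length(iy) || !length(iz))
    stopf("timespace_projection: box selects no voxels")
  nt <- length(movie$t_edges) - 1L
  g <- apply(movie$green$counts[ix, iy, iz, , drop = FALSE], c(1, 4), sum)
  r <- apply(movie$red$counts[ix, iy, iz, , drop = FALSE], c(1, 4), sum)
  dw <- apply(movie$dwell[ix, iy, iz, , drop = FALSE], c(1, 4), sum)
  ratio <- ifelse(dw > 0 & r > 0, g / r, NA_real_)
  med <- stats::median(ratio, na.rm = TRUE)
  structure(list(map = ratio / med, x_um = xc[ix],
                 t_s = (movie$t_edges[-1] + movie$t_edges[-(nt + 1)]) / 2),
            class = "timespace_map")
}

#' Stride-phase averaged fluorescence cube
#'
#' Bins z-projected, dwell-adjusted photon counts (and scan dwell) by
#' in-plane position and stride phase, pooling all strides of one behavior
#' state: the (x, y, phi) cube of mean fluorescence rate over the cycle.
#'
#' @param events located (corrected) event table of one channel.
#' @param samples the matching sample table.
#' @param cfg the [scan_config()].
#' @param clock a `phase_clock` covering the used epochs (time-to-phase by
#'   interpolation).
#' @param strides stride table (`start`, `end`); only photons within
#'   strides are used.
#' @param n_bins phase bins (default 24, i.e., 15 degrees).
#' @param geometry in-plane geometry: list with `origin`, `spacing`,
#'   `dims` (x, y; the third element is ignored).
#' @return object of class `stride_cube`: `rate` array (nx, ny, n_bins),
#'   `counts`, `dwell`, bin centers `phi`, coordinates `x_um`, `y_um`,
#'   `n_strides`.
#' @export
stride_average <- function(events, samples, cfg, clock, strides,
                           n_bins = 24L, geometry) {
  stopifnot(inherits(cfg, "scan_config"))
  if (nrow(strides) < 2L) stopf("stride_average: need at least 2 strides")
  n_bins <- as.integer(n_bins)
  in_stride <- function(t) {
    ok <- rep(FALSE, length(t))
    for (i in seq_len(nrow(strides)))
      ok <- ok | (t >= strides$start[i] & t < strides$end[i])
    ok
  }
  phase_of <- function(t)
    (stats::approx(clock$t_s, clock$phi_unwrapped, xout = t,
                   rule = 2)$y) %% (2 * pi)
  ev <- events[in_stride(events$t_s), , drop = FALSE]
  sm <- samples[in_stride(samples$t_s), , drop = FALSE]
  w <- dwell_adjust(if ("weight" %in% names(ev)) ev$weight
                    else rep(1, nrow(ev)), ev$phi_rad, cfg)
  keep <- !is.na(w)
  dims <- c(geometry$dims[1:2], n_bins)
  org <- c(geometry$origin[1:2], 0)
  sp <- c(geometry$spacing[1:2], 2 * pi / n_bins)
  counts <- hist_nd(cbind(ev$x_um, ev$y_um, phase_of(ev$t_s))[keep, ,
                                                              drop = FALSE],
                    w[keep], org, sp, dims)
  loc <- emission_location(sm, cfg)
  line_t <- 1 / (2 * cfg$f_tag)
  dwell <- hist_nd(cbind(loc$x_um, loc$y_um, phase_of(sm$t_s)),
                   rep(line_t, nrow(sm)), org, sp, dims)
  rate <- counts / dwell
  rate[dwell == 0] <- NA_real_
  n_empty <- sum(apply(dwell, 3, sum) == 0)
  if (n_empty > 0)
    warning(sprintf("stride_average: %d empty phase bins", n_empty),
            call. = FALSE)
  structure(list(
    rate = rate, counts = counts, dwell = dwell,
    phi = (seq_len(n_bins) - 0.5) * 2 * pi / n_bins,
    x_um = org[1] + (seq_len(dims[1]) - 0.5) * sp[1],
    y_um = org[2] + (seq_len(dims[2]) - 0.5) * sp[2],
    n_strides = nrow(strides)
  ), class = "stride_cube")
}

#' Build a stride cube directly from arrays (for analysis of external data)
#'
#' @param rate array (nx, ny, n_bins).
#' @param x_um,y_um coordinates; defaults are unit-spaced.
#' @return a `stride_cube`.
#' @export
stride_cube <- function(rate, x_um = NULL, y_um = NULL) {
  d <- dim(rate)
  structure(list(rate = rate, counts = NULL, dwell = NULL,
                 phi = (seq_len(d[3]) - 0.5) * 2 * pi / d[3],
                 x_um = if (is.null(x_um)) seq_len(d[1]) else x_um,
                 y_um = if (is.null(y_um)) seq_len(d[2]) else y_um,
                 n_strides = NA_integer_),
            class = "stride_cube")
}

#' Complex PCA wave decomposition of a stride cube
#'
#' PCA of the per-point mean-subtracted temporal (phase) signals, spatial
#' points as observations. If a traveling wave dominates, the first two
#' components are sinusoids 90 degrees apart; they are ordered so `c1`
#' leads `c2` (fundamental-frequency cross-spectrum phase +90 degrees) and
#' signed so `c1(phi = 0) >= 0`. The complex spatial projection
#' `g = s1 + i*s2` carries the wave amplitude `|g|` and phase `arg(g)`
#' per point.
#'
#' @param cube a `stride_cube`.
#' @param lowpass_sigma_um optional spatial Gaussian (um) applied to the
#'   complex projection before phase display (`phase_map`).
#' @return object of class `wave_decomposition`: `c1`, `c2` (orthonormal,
#'   length n_bins), complex `C`, complex `g` (nx x ny, NA where the cube
#'   is unsampled), `phase_map`, `var_frac2` (variance share of the first
#'   two components), plus the cube geometry.
#' @export
wave_pca <- function(cube, lowpass_sigma_um = 3) {
  stopifnot(inherits(cube, "stride_cube"))
  d <- dim(cube$rate)
  nb <- d[3]
  if (nb < 3L) stopf("wave_pca: need at least 3 phase bins")
  X <- matrix(cube$rate, d[1] * d[2], nb)
  ok <- rowSums(!is.finite(X)) == 0L
  if (sum(ok) < 10L) stopf("wave_pca: need at least 10 fully sampled points")
  Xc <- X[ok, , drop = FALSE]
  Xc <- Xc - rowMeans(Xc)
  pc <- stats::prcomp(Xc, center = FALSE, scale. = FALSE)
  if (length(pc$sdev) < 2L || pc$sdev[2] == 0)
    stopf("wave_pca: cube is rank deficient")
  c1 <- pc$rotation[, 1]
  c2 <- pc$rotation[, 2]
  # sign fix, then enforce that c1 leads c2 by +90 deg at the fundamental
  if (c1[1] < 0) c1 <- -c1
  f1 <- sum(c1 * exp(-2i * pi * (seq_len(nb) - 1) / nb))
  f2 <- sum(c2 * exp(-2i * pi * (seq_len(nb) - 1) / nb))
  if (Im(f1 * Conj(f2)) < 0) c2 <- -c2
  s1 <- Xc %*% c1
  s2 <- Xc %*% c2
  g <- rep(NA_complex_, d[1] * d[2])
  g[ok] <- s1 + 1i * s2
  gmat <- matrix(g, d[1], d[2])
  ph <- gmat
  if (!is.null(lowpass_sigma_um) && lowpass_sigma_um > 0) {
    sx <- lowpass_sigma_um / diff(cube$x_um[1:2])
    sy <- lowpass_sigma_um / if (length(cube$y_um) > 1)
      diff(cube$y_um[1:2]) else 1
    re <- matrix(Re(gmat), d[1], d[2]); im <- matrix(Im(gmat), d[1], d[2])
    re[is.na(re)] <- 0; im[is.na(im)] <- 0
    msk <- gauss_smooth_nd(matrix(as.numeric(!is.na(gmat)), d[1], d[2]),
                           c(sx, sy))
    re <- gauss_smooth_nd(re, c(sx, sy)) / pmax(msk, 1e-9)
    im <- gauss_smooth_nd(im, c(sx, sy)) / pmax(msk, 1e-9)
    ph <- matrix(complex(real = re, imaginary = im), d[1], d[2])
    ph[is.na(gmat)] <- NA_complex_
  }
  tot <- sum(pc$sdev^2)
  structure(list(
    c1 = c1, c2 = c2, C = c1 + 1i * c2, g = gmat,
    phase_map = Arg(ph), amplitude = abs(gmat),
    var_frac2 = sum(pc$sdev[1:2]^2) / tot,
    phi = cube$phi, x_um = cube$x_um, y_um = cube$y_um
  ), class = "wave_decomposition")
}

#' Variance explained by a plane-wave-restricted projection
#'
#' Keeps the PCA amplitude map `|g|` but restricts the phase to that of a
#' plane wave, `arg g = k . (x, y) + phi0`; `k` is fit over a direction
#' grid (5 degree steps) with `|k|` up to `pi/k_max_spacing`, locally
#' refined, and `phi0` solved in closed form for each `k`. Returns
#' `1 - residual/total` variance of the cube after subtracting the
#' wave-restricted reconstruction; negative values mean the plane-wave
#' constraint fits worse than no reconstruction at all.
#'
#' @param cube the `stride_cube` the decomposition came from.
#' @param decomp a [wave_pca()] result.
#' @param k_max_spacing length scale (um) setting the maximum `|k|`
#'   (default 4 um, i.e., wavelengths down to 8 um).
#' @return list of class `wave_fit`: `variance_explained`, `k` (rad/um,
#'   length 2), `phi0`, plus the unrestricted two-component share
#'   `variance_explained_pca`.
#' @export
wave_variance_explained <- function(cube, decomp, k_max_spacing = 4) {
  stopifnot(inherits(decomp, "wave_decomposition"))
  d <- dim(cube$rate)
  nb <- d[3]
  X <- matrix(cube$rate, d[1] * d[2], nb)
  ok <- rowSums(!is.finite(X)) == 0L
  Xc <- X[ok, , drop = FALSE]
  Xc <- Xc - rowMeans(Xc)
  tot <- sum(Xc^2)
  g <- as.vector(decomp$g)[ok]
  if (tot < 1e-24 || all(abs(g) < 1e-12)) {
    return(structure(list(variance_explained = 0, k = c(0, 0), phi0 = 0,
                          variance_explained_pca = 0), class = "wave_fit"))
  }
  xy <- cbind(rep(cube$x_um, length(cube$y_um))[ok],
              rep(cube$y_um, each = length(cube$x_um))[ok])
  amp <- abs(g)
  score <- function(k) {
    # optimal phi0 in closed form: maximize Re(sum |g| g* e^{i(k.x+phi0)})
    z <- sum(amp * Conj(g) * exp(1i * (xy %*% k)))
    Mod(z)
  }
  dirs <- seq(0, 175, by = 5) * pi / 180
  kmax <- pi / k_max_spacing
  mags <- seq(-kmax, kmax, length.out = 41)
  best <- c(0, 0); bestv <- -Inf
  for (th in dirs) {
    u <- c(cos(th), sin(th))
    for (m in mags) {
      v <- score(m * u)
      if (v > bestv) { bestv <- v; best <- m * u }
    }
  }
  o <- stats::optim(best, function(k) -score(k), method = "Nelder-Mead",
                    control = list(maxit = 200, reltol = 1e-10))
  k <- o$par
  z <- sum(amp * Conj(g) * exp(1i * as.numeric(xy %*% k)))
  phi0 <- -Arg(z)
  gw <- amp * exp(1i * (as.numeric(xy %*% k) + phi0))
  # reconstruction Re(gw* C) per point; C rows = phases
  Cr <- Re(decomp$C); Ci <- Im(decomp$C)
  recon <- outer(Re(gw), Cr) + outer(Im(gw), Ci)
  resid <- sum((Xc - recon)^2)
  structure(list(variance_explained = 1 - resid / tot, k = k, phi0 = phi0,
                 variance_explained_pca = decomp$var_frac2),
            class = "wave_fit")
}

#' Per-bout activity statistics and forward/backward comparison
#'
#' Averages the normalized ratiometric trace over each behavioral bout and
#' tests whether backward-bout medians exceed forward-bout medians with a
#' one-sided Wilcoxon rank-sum test (exact for small samples).
#'
#' @param trace a [voi_ratio()] trace for one VOI (columns `t_s`,
#'   `ratio_norm`).
#' @param bouts data frame with `state` ("forward"/"backward"/"other"),
#'   `start`, `end`.
#' @param min_per_state minimum bouts per state for the test.
#' @return list of class `bout_stats`: `per_bout` data frame, group
#'   medians, `p_backward_greater` (NA with a `flag` when too few bouts).
#' @export
bout_stats <- function(trace, bouts, min_per_state = 3L) {
  means <- vapply(seq_len(nrow(bouts)), function(i) {
    sel <- trace$t_s >= bouts$start[i] & trace$t_s < bouts$end[i]
    mean(trace$ratio_norm[sel], na.rm = TRUE)
  }, 0)
  per_bout <- data.frame(state = bouts$state, start = bouts$start,
                         end = bouts$end, mean_ratio = means)
  fb <- per_bout[per_bout$state %in% c("forward", "backward") &
                   is.finite(per_bout$mean_ratio), ]
  med <- tapply(fb$mean_ratio, fb$state, stats::median)
  nf <- sum(fb$state == "forward"); nb <- sum(fb$state == "backward")
  if (nf >= min_per_state && nb >= min_per_state) {
    p <- stats::wilcox.test(fb$mean_ratio[fb$state == "backward"],
                            fb$mean_ratio[fb$state == "forward"],
                            alternative = "greater", exact = (nf <= 10 &&
                                                                nb <= 10))$p.value
    flag <- "ok"
  } else {
    p <- NA_real_
    flag <- "too-few-bouts"
  }
  structure(list(per_bout = per_bout, medians = med,
                 p_backward_greater = p, flag = flag),
            class = "bout_stats")
}
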