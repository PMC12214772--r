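#' Smoothed forward velocity of the tracked neuron
#'
#' Denoises the 2D tracked path with a cubic smoothing spline, then
#' differentiates with a derivative-of-Gaussian filter and projects onto
#' the heading to obtain the signed forward velocity.
#'
#' The smoothing parameter `p` follows the `p*RSS + (1-p)*penalty`
#' convention (penalty on unscaled time in seconds); it is converted to the
#' penalized-RSS form `RSS + lambda*penalty` on time scaled to the unit
#' interval via `lambda = (1-p)/p / L^3` with `L` the trace duration (the
#' curvature integral picks up a factor `L^3` under rescaling).
#'
#' @param track data frame with `t_s`, `x_um`, `y_um` (tracked positions).
#' @param heading data frame with `t_s`, `hx`, `hy` (unit heading vectors),
#'   or a length-2 constant vector.
#' @param p smoothing parameter in the `p*RSS + (1-p)*penalty` convention.
#' @param sigma derivative-of-Gaussian width (s).
#' @param dt resampling interval (s); default the median sample spacing.
#' @return data frame of class `velocity_trace` with `t_s`, `v_fwd_ums`
#'   (um/s) and the smoothed `x_um`, `y_um`.
#' @export
forward_velocity <- function(track, heading, p = 0.99, sigma = 0.25,
                             dt = NULL) {
  stopifnot(all(c("t_s", "x_um", "y_um") %in% names(track)))
  dur <- diff(range(track$t_s))
  if (dur < 3 * 4 * sigma)
    stopf("forward_velocity: trace (%.2f s) shorter than 3 filter widths", dur)
  if (is.null(dt)) dt <- stats::median(diff(track$t_s))
  tt <- seq(min(track$t_s), max(track$t_s), by = dt)
  L <- diff(range(track$t_s))
  lambda <- (1 - p) / p / L^3
  sm <- function(y) {
    fit <- stats::smooth.spline(track$t_s, y, lambda = lambda,
                                all.knots = FALSE)
    stats::predict(fit, tt)$y
  }
  xs <- sm(track$x_um)
  ys <- sm(track$y_um)
  # derivative-of-Gaussian filter, normalized to recover a unit ramp slope
  r <- ceiling(4 * sigma / dt)
  u <- seq(-r, r) * dt
  k <- -u * exp(-u^2 / (2 * sigma^2))
  k <- k / sum(-u * k)            # unit response to a unit-slope ramp
  dfilt <- function(y) {
    yp <- c(rep(y[1], r), y, rep(y[length(y)], r))
    as.numeric(stats::filter(yp, k, sides = 2))[(r + 1):(r + length(y))]
  }
  vx <- dfilt(xs)
  vy <- dfilt(ys)
  if (is.numeric(heading) && length(heading) == 2L) {
    hx <- rep(heading[1], length(tt)); hy <- rep(heading[2], length(tt))
  } else {
    idx <- pmax(findInterval(tt, heading$t_s), 1L)
    hx <- heading$hx[idx]; hy <- heading$hy[idx]
  }
  nrm <- sqrt(hx^2 + hy^2)
  out <- data.frame(t_s = tt, v_fwd_ums = vx * hx / nrm + vy * hy / nrm,
                    x_um = xs, y_um = ys)
  class(out) <- c("velocity_trace", "data.frame")
  out
}

#' Hilbert phase clock from a velocity trace
#'
#' Associates a phase with the quasi-periodic forward velocity via the
#' analytic signal. In forward mode the phase is 0 at local maxima of the
#' forward velocity (peak in-travel-direction brain speed); in backward
#' mode the sign of the velocity is flipped first, so the phase is 0 at
#' peak backward speed. The raw analytic-signal phase is remapped to
#' increase by `2*pi` per cycle.
#'
#' @param v a [forward_velocity()] trace (or data frame with `t_s`,
#'   `v_fwd_ums`), restricted to one bout.
#' @param mode `"forward"` or `"backward"`.
#' @return data frame of class `phase_clock` with `t_s`, `phi_rad`
#'   (wrapped to `[0, 2*pi)`) and `phi_unwrapped`.
#' @export
hilbert_phase <- function(v, mode = c("forward", "backward")) {
  mode <- match.arg(mode)
  vv <- v$v_fwd_ums
  if (stats::sd(vv) < 1e-9 * (abs(mean(vv)) + 1e-12) || stats::sd(vv) == 0)
    stopf("hilbert_phase: velocity is (nearly) constant; phase is degenerate")
  s <- if (mode == "forward") vv else -vv
  # analytic pair (s, H(-s)): phase 0 at maxima of s
  a <- analytic_signal(-s)
  raw <- atan2(Im(a), s)
  unw <- raw
  d <- diff(raw)
  d <- d - 2 * pi * round(d / (2 * pi))
  unw <- cumsum(c(raw[1], d))
  if (unw[length(unw)] < unw[1]) unw <- -unw
  out <- data.frame(t_s = v$t_s, phi_rad = unw %% (2 * pi),
                    phi_unwrapped = unw)
  class(out) <- c("phase_clock", "data.frame")
  out
}

#' Segment strides from a phase clock
#'
#' Strides span consecutive upward crossings of `phi = 0` (multiples of
#' `2*pi` of the unwrapped phase). The last stride of each bout is
#' excluded.
#'
#' @param clock a [hilbert_phase()] clock (one bout).
#' @param drop_last drop the final stride (default, per-bout exclusion).
#' @param edge_tol phase tolerance (rad) for counting a crossing that falls
#'   (numerically) just outside the recorded span, e.g. a bout starting
#'   exactly at peak speed.
#' @return data frame with `start`, `end` (s) and `k` (cycle index);
#'   zero rows when fewer than 2 crossings exist.
#' @export
segment_strides <- function(clock, drop_last = TRUE, edge_tol = 0.3) {
  unw <- clock$phi_unwrapped
  tt <- clock$t_s
  k0 <- ceiling((unw[1] - edge_tol) / (2 * pi))
  k1 <- floor((unw[length(unw)] + edge_tol) / (2 * pi))
  if (k1 - k0 < 1)
    return(data.frame(start = numeric(0), end = numeric(0), k = integer(0)))
  cross <- vapply(k0:k1, function(k) {
    i <- which(unw >= 2 * pi * k)[1]
    if (is.na(i)) return(tt[length(tt)])   # edge-tolerated final crossing
    if (i == 1L) return(tt[1])
    # linear interpolation of the crossing time
    tt[i - 1] + (2 * pi * k - unw[i - 1]) / (unw[i] - unw[i - 1]) *
      (tt[i] - tt[i - 1])
  }, 0)
  st <- data.frame(start = cross[-length(cross)], end = cross[-1],
                   k = (k0:k1)[-length(cross)])
  if (drop_last && nrow(st) > 0) st <- st[-nrow(st), , drop = FALSE]
  st
}

# evaluate the 4-control-value b-spline phase adjustment at phases phi
warp_delta <- function(theta, phi) {
  B <- splines::bs(pmin(pmax(phi, 0), 2 * pi), df = 4, intercept = TRUE,
                   Boundary.knots = c(0, 2 * pi))
  as.numeric(B %*% theta)
}

#' Align strides to a velocity template by b-spline time warping
#'
#' Resamples each stride's velocity onto a phase grid (extended by `pi/4`
#' into the neighboring strides where available), forms the template as the
#' across-stride mean on `(0, 2*pi)`, and fits a 4-control-value b-spline
#' phase adjustment `delta_phi(phi; theta)` per stride minimizing the
#' squared distance to the template, with `|delta_phi| < pi/4` (enforced by
#' bounding the control values; the basis is a partition of unity). The
#' adjusted phases are mapped back to the time axis with a cross-fade to
#' zero adjustment over `pi/8` at the stride joins, and the global clock is
#' made non-decreasing.
#'
#' @param clock a [hilbert_phase()] clock.
#' @param v the matching [forward_velocity()] trace.
#' @param strides a [segment_strides()] table (uses the cycle index `k`).
#' @param n_grid phase-grid resolution.
#' @return list of class `stride_warp`: `template` (data frame `phi`,
#'   `v`), `theta` (strides x 4), `clock` (refined `phase_clock`),
#'   `max_delta` per stride, and `flag`.
#' @export
warp_align <- function(clock, v, strides, n_grid = 96L) {
  ns <- nrow(strides)
  if (ns < 3L) stopf("warp_align: need at least 3 strides")
  phig <- seq(0, 2 * pi, length.out = n_grid + 1L)[-(n_grid + 1L)] +
    pi / n_grid
  # per-stride velocity vs phase, interpolated on the unwrapped clock
  vi <- matrix(NA_real_, ns, length(phig))
  for (i in seq_len(ns)) {
    target <- 2 * pi * strides$k[i] + phig
    ok <- target >= min(clock$phi_unwrapped) &
      target <= max(clock$phi_unwrapped)
    vi[i, ok] <- stats::approx(clock$phi_unwrapped, v$v_fwd_ums,
                               xout = target[ok])$y
  }
  template <- colMeans(vi, na.rm = TRUE)
  interp_stride <- function(i, phi_q) {
    target <- 2 * pi * strides$k[i] +
      pmin(pmax(phi_q, -pi / 4), 2 * pi + pi / 4)
    stats::approx(clock$phi_unwrapped, v$v_fwd_ums, xout = target,
                  rule = 2)$y
  }
  theta <- matrix(0, ns, 4)
  max_delta <- numeric(ns)
  for (i in seq_len(ns)) {
    obj <- function(th) {
      vq <- interp_stride(i, phig + warp_delta(th, phig))
      sum((vq - template)^2)
    }
    o <- stats::optim(rep(0, 4), obj, method = "L-BFGS-B",
                      lower = -pi / 4 + 1e-6, upper = pi / 4 - 1e-6,
                      control = list(maxit = 100))
    theta[i, ] <- o$par
    max_delta[i] <- max(abs(warp_delta(o$par, phig)))
  }
  at_bound <- mean(max_delta > pi / 4 - 1e-3) > 0.5
  if (at_bound)
    warning("warp_align: over half the strides hit the |delta_phi| bound; template mismatch?",
            call. = FALSE)
  # refined global clock: apply the tapered adjustment within each stride
  unw <- clock$phi_unwrapped
  phi_new <- unw
  taper <- function(phi) {
    w <- pmin(phi, 2 * pi - phi) / (pi / 8)
    pmin(pmax(w, 0), 1)
  }
  for (i in seq_len(ns)) {
    base <- 2 * pi * strides$k[i]
    sel <- unw >= base & unw < base + 2 * pi
    if (!any(sel)) next
    ph <- unw[sel] - base
    phi_new[sel] <- base + ph + warp_delta(theta[i, ], ph) * taper(ph)
  }
  phi_new <- cummax(phi_new)
  rclock <- data.frame(t_s = clock$t_s, phi_rad = phi_new %% (2 * pi),
                       phi_unwrapped = phi_new)
  class(rclock) <- c("phase_clock", "data.frame")
  list(template = data.frame(phi = phig, v = template),
       theta = theta, clock = rclock, max_delta = max_delta,
       flag = if (at_bound) "bound" else "ok")
}
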