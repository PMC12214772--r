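#' Scan configuration
#'
#' Bundles the user-level parameters that determine the in-plane galvo
#' waveforms and the resonant axial (TAG lens) scan. The in-plane pattern is
#' a "Pong" scan: both galvos are driven with triangle waves whose
#' frequencies are locked to the golden ratio, so the trajectory fills the
#' field without repeating, while the triangle profile (unlike a sinusoidal
#' Lissajous scan) distributes dwell time uniformly across the field.
#'
#' @param a_x full peak-to-peak x scan range (um).
#' @param r_xy aspect ratio; the y range is `a_x / r_xy` (>= 1).
#' @param tau_min minimum pixel dwell time (s).
#' @param dx target pixel size (um).
#' @param f_max maximum galvo frequency (Hz).
#' @param f_fpga FPGA clock frequency (Hz).
#' @param f_tag TAG lens resonance frequency (Hz); one axial line takes
#'   `1/(2*f_tag)` seconds.
#' @param A_tag axial scan half-amplitude (um); focal depth is
#'   `A_tag*cos(phi)`.
#' @param phi_exclude half-angle (degrees) of the TAG phase band around the
#'   axial turnarounds (`phi = 0` and `pi`) excluded from reconstruction.
#' @param norm_const normalization constant for the axial dwell-time count
#'   adjustment; see [dwell_adjust()].
#' @return an object of class `scan_config`.
#' @seealso [nominal_frequencies()], [pong_trajectory()], [coverage_stats()]
#' @export
scan_config <- function(a_x = 200, r_xy = 1, tau_min = 3e-6, dx = 0.8,
                        f_max = 1000, f_fpga = 8e7, f_tag = 1.9e5,
                        A_tag = 25, phi_exclude = 20, norm_const = 0.7846) {
  if (a_x <= 0 || dx <= 0 || tau_min <= 0 || f_max <= 0 || f_fpga <= 0)
    stopf("scan_config: a_x, dx, tau_min, f_max and f_fpga must be positive")
  if (r_xy < 1) stopf("scan_config: aspect ratio r_xy must be >= 1")
  if (dx >= a_x) stopf("scan_config: pixel size dx must be smaller than a_x")
  if (f_tag <= 0) stopf("scan_config: f_tag must be positive")
  if (phi_exclude < 0 || phi_exclude >= 90)
    stopf("scan_config: phi_exclude must lie in [0, 90)")
  structure(list(
    a_x = a_x, r_xy = r_xy, tau_min = tau_min, dx = dx, f_max = f_max,
    f_fpga = f_fpga, f_tag = f_tag, A_tag = A_tag,
    phi_exclude = phi_exclude, norm_const = norm_const
  ), class = "scan_config")
}

#' Nominal Pong scan frequencies
#'
#' The x frequency is the fastest triangle wave that still dwells `tau_min`
#' per pixel of size `dx` (clamped at `f_max`); the y frequency is locked to
#' it by the golden ratio, `y = 2/(1+sqrt(5)) * x`, making the two waves
#' incommensurate.
#'
#' @param cfg a [scan_config()].
#' @return list with `x_freq` and `y_freq` in Hz.
#' @export
nominal_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "scan_config"))
  x_freq <- min(cfg$dx / (2 * cfg$a_x * cfg$tau_min), cfg$f_max)
  list(x_freq = x_freq, y_freq = 2 / (1 + sqrt(5)) * x_freq)
}

#' Nearest prime number
#'
#' Returns the prime closest to `v`; ties between equidistant primes are
#' broken toward the larger prime (the lower resulting scan frequency).
#'
#' @param v a number >= 2.
#' @return an integer prime.
#' @export
nearest_prime <- function(v) {
  if (!is.numeric(v) || length(v) != 1L || v < 2)
    stopf("nearest_prime is defined for single values >= 2")
  lo <- floor(v)
  hi <- ceiling(v)
  while (lo >= 2 && !pracma::isprime(lo)) lo <- lo - 1
  while (!pracma::isprime(hi)) hi <- hi + 1
  if (lo < 2) return(as.integer(hi))
  # tie -> larger prime
  if (v - lo < hi - v) as.integer(lo) else as.integer(hi)
}

#' Quantize galvo step intervals to FPGA counter values
#'
#' The FPGA advances each triangle wave by one pixel (`dx`) every rollover
#' of an integer counter at the FPGA clock. The ideal step intervals are
#' `dtau_x = dx/(2*a_x)/x_freq` and `dtau_y = dtau_x*(1+sqrt(5))/2`; the
#' counter values are the nearest primes to `f_fpga * dtau`, which keeps the
#' joint (x, y) pattern from repeating more often than the discrete logic
#' requires.
#'
#' @param cfg a [scan_config()].
#' @param x_freq,y_freq nominal frequencies (Hz); default from
#'   [nominal_frequencies()].
#' @return list with elements `x` and `y`, each a `galvo_waveform` list with
#'   `freq_nominal`, `freq_effective`, `counter`, `step` (um) and
#'   `steps_per_period`.
#' @export
quantize_counters <- function(cfg, x_freq = NULL, y_freq = NULL) {
  stopifnot(inherits(cfg, "scan_config"))
  if (is.null(x_freq)) {
    nf <- nominal_frequencies(cfg)
    x_freq <- nf$x_freq
    y_freq <- nf$y_freq
  } else if (is.null(y_freq)) {
    y_freq <- 2 / (1 + sqrt(5)) * x_freq
  }
  dtau_x <- cfg$dx / (2 * cfg$a_x) / x_freq
  dtau_y <- dtau_x * GOLDEN
  steps_x <- 2 * cfg$a_x / cfg$dx
  steps_y <- 2 * cfg$a_x / (cfg$r_xy * cfg$dx)
  if (steps_x < 2 || steps_y < 2)
    stopf("quantize_counters: fewer than 2 steps per period; enlarge a_x or shrink dx")
  mk <- function(freq, dtau, steps) {
    ctr <- nearest_prime(cfg$f_fpga * dtau)
    structure(list(
      freq_nominal = freq,
      freq_effective = cfg$f_fpga / (ctr * steps),
      counter = ctr,
      step = cfg$dx,
      steps_per_period = steps
    ), class = "galvo_waveform")
  }
  list(x = mk(x_freq, dtau_x, steps_x), y = mk(y_freq, dtau_y, steps_y))
}

# Quantized triangle position at times t for one axis: the position advances
# by `step` um every `counter` FPGA ticks. Centered on 0; full peak-to-peak
# range is steps_per_period*step/2.
tri_steps <- function(t, counter, f_fpga, steps_per_period, step) {
  j <- floor(t * f_fpga / counter)
  ph <- j %% steps_per_period
  k <- ifelse(ph <= steps_per_period / 2, ph, steps_per_period - ph)
  k * step - steps_per_period * step / 4
}

#' Continuous triangle wave
#'
#' `tri(theta) = 2/pi * asin(sin(theta))`: 1 at `pi/2`, 0 at `pi`, -1 at
#' `3*pi/2`.
#'
#' @param theta angle (rad).
#' @return value in `[-1, 1]`.
#' @export
tri_wave <- function(theta) 2 / pi * asin(sin(theta))

#' Generate a Pong scan trajectory
#'
#' Emits one sample per TAG half-period (one axial line), at the line
#' midpoint. In-plane positions follow the FPGA-quantized triangle waves;
#' `phi` is the TAG phase and `z = A_tag * cos(phi)`. Positions are relative
#' to the tracked reference (field center).
#'
#' @param cfg a [scan_config()].
#' @param duration trajectory duration (s).
#' @return a `data.frame` of class `scan_trajectory` with columns `t_s`,
#'   `x_um`, `y_um`, `phi_rad`, `z_um` and attributes `kind` and `cfg`.
#' @export
pong_trajectory <- function(cfg, duration) {
  stopifnot(inherits(cfg, "scan_config"))
  if (duration <= 0) stopf("pong_trajectory: duration must be positive")
  qc <- quantize_counters(cfg)
  line_t <- 1 / (2 * cfg$f_tag)
  n <- floor(duration / line_t)
  t <- (seq_len(n) - 0.5) * line_t
  x <- tri_steps(t, qc$x$counter, cfg$f_fpga, qc$x$steps_per_period, cfg$dx)
  y <- tri_steps(t, qc$y$counter, cfg$f_fpga, qc$y$steps_per_period,
                 cfg$dx)
  phi <- (2 * pi * cfg$f_tag * t) %% (2 * pi)
  traj <- data.frame(t_s = t, x_um = x, y_um = y, phi_rad = phi,
                     z_um = cfg$A_tag * cos(phi))
  attr(traj, "kind") <- "pong"
  attr(traj, "cfg") <- cfg
  class(traj) <- c("scan_trajectory", "data.frame")
  traj
}

#' Generate a bidirectional raster reference trajectory
#'
#' One x line per y row: x sweeps the full range as a triangle at the
#' nominal `x_freq` while y steps one pixel per half-period, covering the y
#' range in `a_x/(r_xy*dx)` lines, then retraces. Used as the conventional
#' comparison for coverage statistics.
#'
#' @inheritParams pong_trajectory
#' @return a `scan_trajectory` data frame (kind `"raster"`).
#' @export
raster_trajectory <- function(cfg, duration) {
  stopifnot(inherits(cfg, "scan_config"))
  if (duration <= 0) stopf("raster_trajectory: duration must be positive")
  nf <- nominal_frequencies(cfg)
  line_t <- 1 / (2 * cfg$f_tag)
  n <- floor(duration / line_t)
  t <- (seq_len(n) - 0.5) * line_t
  # phase-shift the triangle so each line is one full monotone sweep
  x <- cfg$a_x / 2 * tri_wave(2 * pi * nf$x_freq * t + pi / 2)
  x_line_t <- 1 / (2 * nf$x_freq)          # one unidirectional x sweep
  ny <- round(cfg$a_x / (cfg$r_xy * cfg$dx))
  row <- floor(t / x_line_t) %% ny
  y <- -cfg$a_x / (2 * cfg$r_xy) + (row + 0.5) * cfg$dx
  phi <- (2 * pi * cfg$f_tag * t) %% (2 * pi)
  traj <- data.frame(t_s = t, x_um = x, y_um = y, phi_rad = phi,
                     z_um = cfg$A_tag * cos(phi))
  attr(traj, "kind") <- "raster"
  attr(traj, "cfg") <- cfg
  class(traj) <- c("scan_trajectory", "data.frame")
  traj
}

#' Characteristic bidirectional raster time
#'
#' The time a conventional bidirectional raster needs to sample the full
#' field once at pixel density `dx`: number of raster lines
#' (`a_x/(r_xy*dx)`) divided by the bidirectional line rate (`2*x_freq`).
#' Used as the reference time scale for Pong coverage and as the movie time
#' base.
#'
#' @param cfg a [scan_config()].
#' @param x_freq x galvo frequency (Hz); default nominal.
#' @return time in seconds.
#' @export
raster_characteristic_time <- function(cfg, x_freq = NULL) {
  stopifnot(inherits(cfg, "scan_config"))
  if (is.null(x_freq)) x_freq <- nominal_frequencies(cfg)$x_freq
  (cfg$a_x / cfg$r_xy / cfg$dx) / (2 * x_freq)
}

#' Axial focal position of the TAG lens
#'
#' @param phi TAG phase (rad).
#' @param A axial half-amplitude (um).
#' @param z_off offset of the tracked reference below the natural focal
#'   plane (um).
#' @return `z = A*cos(phi) - z_off` (um).
#' @export
tag_axial_position <- function(phi, A, z_off = 0) A * cos(phi) - z_off

#' Sample displacement during one axial line
#'
#' How far a sample moving at `speed` travels during a single direction of
#' the axial scan (`1/(2*f_tag)` seconds) -- the motion blur floor of the
#' axial line time.
#'
#' @param speed sample speed (um/s).
#' @param f_tag TAG frequency (Hz).
#' @return displacement in um.
#' @export
motion_per_axial_line <- function(speed, f_tag = 2e5) speed / (2 * f_tag)

#' Time to cover a pixel grid with one axial line per pixel
#'
#' @param nx,ny number of x-y pixels.
#' @param f_tag TAG frequency (Hz).
#' @return list with `frame_time` (s) and `rate` (volumes/s).
#' @export
volume_frame_time <- function(nx, ny, f_tag = 2e5) {
  ft <- nx * ny / (2 * f_tag)
  list(frame_time = ft, rate = 1 / ft)
}

#' Coverage statistics of a scan trajectory
#'
#' Bins the in-plane samples within `[0, T]` onto a pixel grid spanning the
#' configured scan ranges and reports the fraction of pixels visited and the
#' per-pixel staleness (time since last visit).
#'
#' @param traj a `scan_trajectory`.
#' @param pixel pixel edge (um).
#' @param T time horizon (s); must not exceed the trajectory duration.
#' @return list of class `coverage_report` with `fraction`, `staleness`
#'   (matrix, `NA` where never visited), `first_visit` (matrix) and
#'   `full_coverage_time` (`NA` if never complete).
#' @export
coverage_stats <- function(traj, pixel, T = max(traj$t_s)) {
  stopifnot(inherits(traj, "scan_trajectory"))
  cfg <- attr(traj, "cfg")
  if (T > max(traj$t_s) + 1e-12)
    stopf("coverage_stats: T exceeds the trajectory duration")
  if (pixel < cfg$dx / 2)
    warning("coverage pixel is below half the scan step; resolution is limited by dx",
            call. = FALSE)
  keep <- traj$t_s <= T
  x <- traj$x_um[keep]; y <- traj$y_um[keep]; t <- traj$t_s[keep]
  # the beam moves continuously between per-line samples: supersample the
  # path so consecutive points differ by less than half a pixel
  if (length(x) > 1L) {
    step <- max(max(abs(diff(x))), max(abs(diff(y))))
    M <- ceiling(step / (pixel / 2))
    if (M > 1L) {
      n0 <- length(x)
      f <- (seq_len(M) - 1L) / M
      i0 <- rep(seq_len(n0 - 1L), each = M)
      fr <- rep(f, n0 - 1L)
      x <- c(x[i0] + fr * (x[i0 + 1L] - x[i0]), x[n0])
      y <- c(y[i0] + fr * (y[i0 + 1L] - y[i0]), y[n0])
      t <- c(t[i0] + fr * (t[i0 + 1L] - t[i0]), t[n0])
    }
  }
  npx <- max(1L, round(cfg$a_x / pixel))
  npy <- max(1L, round(cfg$a_x / cfg$r_xy / pixel))
  ix <- pmin(pmax(floor((x + cfg$a_x / 2) / pixel), 0), npx - 1L)
  iy <- pmin(pmax(floor((y + cfg$a_x / (2 * cfg$r_xy)) / pixel), 0), npy - 1L)
  idx <- ix + npx * iy + 1L
  first <- rep(NA_real_, npx * npy)
  last <- rep(NA_real_, npx * npy)
  o <- order(t)
  # first/last visit per pixel via ordered assignment
  first[idx[o][!duplicated(idx[o])]] <- t[o][!duplicated(idx[o])]
  ro <- rev(o)
  last[idx[ro][!duplicated(idx[ro])]] <- t[ro][!duplicated(idx[ro])]
  frac <- mean(!is.na(first))
  structure(list(
    fraction = frac,
    first_visit = matrix(first, npx, npy),
    staleness = matrix(T - last, npx, npy),
    full_coverage_time = if (frac == 1) max(first) else NA_real_,
    pixel = pixel, T = T
  ), class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("coverage_report: %.1f%% of %.3g um pixels visited in %.4g s\n",
              100 * x$fraction, x$pixel, x$T))
  if (!is.na(x$full_coverage_time))
    cat(sprintf("  full coverage reached at %.4g s\n", x$full_coverage_time))
  invisible(x)
}
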