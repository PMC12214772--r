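#' Build the scan-sample table for an imaging run
#'
#' Combines a relative scan trajectory (the programmed Pong pattern) with
#' the tracker's position estimates into the per-axial-line sample stream
#' the instrument records: the FPGA adds the tracked-cell estimate to the
#' galvo targets so the imaged volume stays centered on the tracked neuron.
#'
#' @param traj a [pong_trajectory()] (positions relative to the tracked
#'   reference).
#' @param track `NULL` (stationary reference at the origin) or a data frame
#'   with columns `t_s`, `x_um`, `y_um`, `z_um` of tracker estimates (e.g.,
#'   the `est_*` columns of a [closed_loop_track()] record). Lookup is
#'   nearest-preceding-sample.
#' @return data frame with columns `t_s`, `x_galvo_um`, `y_galvo_um`,
#'   `x_tracker_um`, `y_tracker_um`, `z_tracker_um`, `phi_rad`, `z_off_um`.
#' @export
make_scan_samples <- function(traj, track = NULL) {
  stopifnot(inherits(traj, "scan_trajectory"))
  n <- nrow(traj)
  if (is.null(track)) {
    xt <- yt <- zt <- numeric(n)
  } else {
    stopifnot(all(c("t_s", "x_um", "y_um", "z_um") %in% names(track)))
    idx <- pmax(findInterval(traj$t_s, track$t_s), 1L)
    xt <- track$x_um[idx]; yt <- track$y_um[idx]; zt <- track$z_um[idx]
  }
  out <- data.frame(
    t_s = traj$t_s,
    x_galvo_um = traj$x_um + xt, y_galvo_um = traj$y_um + yt,
    x_tracker_um = xt, y_tracker_um = yt, z_tracker_um = zt,
    phi_rad = traj$phi_rad, z_off_um = 0)
  attr(out, "cfg") <- attr(traj, "cfg")
  out
}

#' Demultiplex photons by arrival phase
#'
#' The imaging and tracking pulse trains are displaced by half a laser
#' period; a photon whose arrival phase falls in the half-period window
#' starting at 0 is assigned to the imaging path, in the window starting at
#' `offset` to the tracking path.
#'
#' @param arrival_phase phase within the laser period (ns).
#' @param laser_period laser repetition period (ns; default 70 MHz).
#' @param offset displacement of the tracking pulse train (ns).
#' @return character vector, `"imaging"` or `"tracking"`.
#' @export
demultiplex <- function(arrival_phase, laser_period = 1e9 / 7e7,
                        offset = 7.1) {
  if (laser_period <= 0) stopf("demultiplex: laser_period must be positive")
  ph <- arrival_phase %% laser_period
  ifelse(ph < laser_period / 2, "imaging", "tracking")
}

#' Emission locations of scan samples
#'
#' Maps galvo/tracker state to the focal position relative to the tracked
#' neuron: `x = x_galvo - x_tracker`, `y = y_galvo - y_tracker`,
#' `z = A_tag*cos(phi) - z_off`. In raw mode the tracker subtraction is
#' omitted (uncorrected lab-frame in-plane positions).
#'
#' @param samples a [make_scan_samples()] table.
#' @param cfg the [scan_config()].
#' @param raw logical; skip the tracker subtraction.
#' @return data frame with `x_um`, `y_um`, `z_um`.
#' @export
emission_location <- function(samples, cfg, raw = FALSE) {
  stopifnot(inherits(cfg, "scan_config"))
  z <- cfg$A_tag * cos(samples$phi_rad) - samples$z_off_um
  if (raw)
    data.frame(x_um = samples$x_galvo_um, y_um = samples$y_galvo_um, z_um = z)
  else
    data.frame(x_um = samples$x_galvo_um - samples$x_tracker_um,
               y_um = samples$y_galvo_um - samples$y_tracker_um, z_um = z)
}

#' Locate photon events on the scan path
#'
#' Assigns each photon the beam state of the nearest preceding scan sample
#' (axial line) and computes its emission location; the TAG phase at the
#' photon's own arrival time gives sub-line axial resolution.
#'
#' @param events photon table with `t_s` (and any other columns, carried
#'   through).
#' @param samples a [make_scan_samples()] table.
#' @param cfg the [scan_config()].
#' @param raw logical; skip the tracker subtraction (uncorrected
#'   reconstruction).
#' @return `events` with added `x_um`, `y_um`, `z_um`, `phi_rad`.
#' @export
locate_events <- function(events, samples, cfg, raw = FALSE) {
  stopifnot(inherits(cfg, "scan_config"))
  line_start <- samples$t_s - 1 / (4 * cfg$f_tag)
  idx <- findInterval(events$t_s, line_start)
  if (any(idx < 1L) || any(events$t_s > max(samples$t_s) + 1 / (2 * cfg$f_tag)))
    stopf("locate_events: photon times fall outside the sample stream (unaligned streams?)")
  phi <- (2 * pi * cfg$f_tag * events$t_s) %% (2 * pi)
  events$phi_rad <- phi
  z <- cfg$A_tag * cos(phi) - samples$z_off_um[idx]
  if (raw) {
    events$x_um <- samples$x_galvo_um[idx]
    events$y_um <- samples$y_galvo_um[idx]
  } else {
    events$x_um <- samples$x_galvo_um[idx] - samples$x_tracker_um[idx]
    events$y_um <- samples$y_galvo_um[idx] - samples$y_tracker_um[idx]
  }
  events$z_um <- z
  events
}

#' Axial dwell-time normalization constant
#'
#' The nominal value (0.7846) normalizes the `|sin(phi)|` count adjustment
#' over a typical phase binning that excludes the turnaround band; the
#' `"uniform_phi"` method recomputes it as the mean of `|sin(phi)|` over the
#' included band, assuming uniform sampling in phase.
#'
#' @param phi_exclude turnaround exclusion half-angle (degrees).
#' @param method `"nominal"` or `"uniform_phi"`.
#' @return normalization constant.
#' @export
dwell_norm_const <- function(phi_exclude = 20,
                             method = c("nominal", "uniform_phi")) {
  method <- match.arg(method)
  if (method == "nominal") return(0.7846)
  ex <- phi_exclude * pi / 180
  2 * cos(ex) / (pi - 2 * ex)
}

#' Dwell-time count adjustment for the resonant axial scan
#'
#' The TAG lens sweeps `z = A*cos(phi)`, so the time spent in an axial slab
#' scales as `1/|sin(phi)|`; attaching `|sin(phi)|/norm_const` to each
#' photon's count instead of computing per-voxel dwell keeps the z-line
#' averaged intensity invariant under axial translation. Photons within the
#' turnaround exclusion band (`phi` within `phi_exclude` degrees of 0 or
#' `pi`) return `NA` and should be discarded (tallied by the caller).
#'
#' @param n photon counts (usually 1 per event).
#' @param phi TAG phase (rad).
#' @param cfg a [scan_config()] (supplies `phi_exclude` and `norm_const`).
#' @return adjusted counts, `NA` where excluded.
#' @export
dwell_adjust <- function(n, phi, cfg) {
  stopifnot(inherits(cfg, "scan_config"))
  ex <- cfg$phi_exclude * pi / 180
  phi <- phi %% (2 * pi)
  excl <- pmin(phi, abs(phi - pi), abs(phi - 2 * pi)) < ex
  out <- n * abs(sin(phi)) / cfg$norm_const
  out[excl] <- NA_real_
  out
}

#' Reconstruction geometry
#'
#' @param extent length-6: `c(x0, x1, y0, y1, z0, z1)` (um) covered by the
#'   volume.
#' @param spacing voxel edges (um), default `c(1, 1, 2)`.
#' @return list with `origin` (lower corner), `spacing`, `dims`.
#' @export
make_geometry <- function(extent, spacing = c(1, 1, 2)) {
  lo <- extent[c(1, 3, 5)]
  hi <- extent[c(2, 4, 6)]
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)))
  list(origin = lo, spacing = spacing, dims = dims)
}

#' Assemble a rate volume from located photons
#'
#' Divides a 3D histogram of dwell-adjusted photon counts by a dwell-time
#' histogram. The dwell histogram is the 2D histogram of in-plane scan-line
#' positions broadcast axially, with `tau = 1/(2*f_tag*n_z)` per voxel per
#' line (the line time split equally over the axial bins). Voxels with zero
#' dwell are missing (rate `NA`).
#'
#' @param events located photon table (from [locate_events()]), one channel.
#' @param samples the matching [make_scan_samples()] table.
#' @param cfg the [scan_config()].
#' @param geometry a [make_geometry()] result.
#' @param epoch optional `c(t0, t1)` time window (s).
#' @param raw logical; use uncorrected in-plane positions for the dwell
#'   histogram too.
#' @return object of class `rate_volume`: arrays `counts`, `dwell`, `rate`
#'   (`NA` where unsampled), the geometry, and a `qc` tally.
#' @export
assemble_volume <- function(events, samples, cfg, geometry,
                            epoch = NULL, raw = FALSE) {
  stopifnot(inherits(cfg, "scan_config"))
  if (!is.null(epoch)) {
    events <- events[events$t_s >= epoch[1] & events$t_s < epoch[2], ,
                     drop = FALSE]
    samples <- samples[samples$t_s >= epoch[1] & samples$t_s < epoch[2], ,
                       drop = FALSE]
  }
  if (nrow(samples) == 0L) {
    warning("assemble_volume: empty epoch; all-missing volume", call. = FALSE)
  }
  n_z <- geometry$dims[3]
  w <- dwell_adjust(if ("weight" %in% names(events)) events$weight
                    else rep(1, nrow(events)), events$phi_rad, cfg)
  n_excl <- sum(is.na(w))
  keep <- !is.na(w)
  counts <- hist_nd(cbind(events$x_um, events$y_um, events$z_um)[keep, ,
                                                                 drop = FALSE],
                    w[keep], geometry$origin, geometry$spacing, geometry$dims)
  loc <- emission_location(samples, cfg, raw = raw)
  d2 <- hist_nd(cbind(loc$x_um, loc$y_um, 0)[, , drop = FALSE],
                rep(1, nrow(samples)),
                c(geometry$origin[1:2], -0.5), c(geometry$spacing[1:2], 1),
                c(geometry$dims[1:2], 1))
  tau <- 1 / (2 * cfg$f_tag * n_z)
  dwell <- array(rep(as.numeric(d2), n_z), geometry$dims) * tau
  rate <- counts / dwell
  rate[dwell == 0] <- NA_real_
  structure(list(counts = counts, dwell = dwell, rate = rate,
                 origin = geometry$origin, spacing = geometry$spacing,
                 dims = geometry$dims, n_z = n_z,
                 qc = list(n_phase_excluded = n_excl,
                           n_outside = attr(counts, "n_dropped"))),
            class = "rate_volume")
}

#' @export
print.rate_volume <- function(x, ...) {
  cat(sprintf("rate_volume %s, %.0f adjusted counts, %.1f%% voxels sampled\n",
              paste(x$dims, collapse = "x"), sum(x$counts),
              100 * mean(x$dwell > 0)))
  invisible(x)
}

#' Assemble a two-channel rate movie
#'
#' Builds 4D (x, y, z, t) count and dwell histograms per channel, convolves
#' both with a separable Gaussian of one voxel standard deviation in every
#' dimension, and divides. The default time bin is half the characteristic
#' raster time.
#'
#' @param events located photon table with a `channel` column.
#' @param samples the matching sample table.
#' @param cfg the [scan_config()].
#' @param geometry a [make_geometry()] result.
#' @param time_bin bin width (s); default `raster_characteristic_time(cfg)/2`.
#' @param smooth logical; apply the 4D Gaussian.
#' @param channels channels to reconstruct.
#' @return object of class `rate_movie`: per channel 4D `counts` and `rate`
#'   arrays, the shared 4D `dwell`, bin edges `t_edges`, and the geometry.
#' @export
assemble_movie <- function(events, samples, cfg, geometry, time_bin = NULL,
                           smooth = TRUE, channels = c("red", "green")) {
  stopifnot(inherits(cfg, "scan_config"))
  if (is.null(time_bin)) time_bin <- raster_characteristic_time(cfg) / 2
  if (time_bin <= 0) stopf("assemble_movie: time_bin must be positive")
  t0 <- 0
  t1 <- max(samples$t_s)
  nt <- max(1L, as.integer(ceiling((t1 - t0) / time_bin)))
  dims4 <- c(geometry$dims, nt)
  org4 <- c(geometry$origin, t0)
  sp4 <- c(geometry$spacing, time_bin)
  loc <- emission_location(samples, cfg)
  d2 <- hist_nd(cbind(loc$x_um, loc$y_um, 0, samples$t_s),
                rep(1, nrow(samples)),
                c(geometry$origin[1:2], -0.5, t0),
                c(geometry$spacing[1:2], 1, time_bin),
                c(geometry$dims[1:2], 1L, nt))
  tau <- 1 / (2 * cfg$f_tag * geometry$dims[3])
  dwell <- array(0, dims4)
  for (k in seq_len(geometry$dims[3]))
    dwell[, , k, ] <- d2[, , 1, ] * tau
  if (smooth) dwell_s <- gauss_smooth_nd(dwell, c(1, 1, 1, 1)) else
    dwell_s <- dwell
  out <- list(dwell = dwell_s, t_edges = t0 + (0:nt) * time_bin,
              origin = geometry$origin, spacing = geometry$spacing,
              dims = geometry$dims, time_bin = time_bin)
  for (ch in channels) {
    ev <- events[events$channel == ch, , drop = FALSE]
    w <- dwell_adjust(if ("weight" %in% names(ev)) ev$weight
                      else rep(1, nrow(ev)), ev$phi_rad, cfg)
    keep <- !is.na(w)
    cnt <- hist_nd(cbind(ev$x_um, ev$y_um, ev$z_um, ev$t_s)[keep, ,
                                                            drop = FALSE],
                   w[keep], org4, sp4, dims4)
    cnt_s <- if (smooth) gauss_smooth_nd(cnt, c(1, 1, 1, 1)) else cnt
    rate <- cnt_s / dwell_s
    rate[dwell_s <= 0] <- NA_real_
    out[[ch]] <- list(counts = cnt_s, rate = rate)
  }
  class(out) <- "rate_movie"
  out
}

#' Smooth, complete template from a rate volume
#'
#' Produces a smooth, strictly non-negative rate field with no missing
#' voxels, robust to outlier voxels, by iteratively reweighted normalized
#' Gaussian convolution: observed voxels are weighted by their dwell times,
#' missing voxels are filled by progressively wider kernels, and an
#' L1-type reweighting pass (weights `1/max(|residual|, eps)`) suppresses
#' outliers. The result can be evaluated at arbitrary continuous
#' coordinates with [template_eval()].
#'
#' @param vol a [assemble_volume()] result.
#' @param sigma base smoothing width (voxels).
#' @param robust_iters number of L1 reweighting passes.
#' @param refine_iters residual back-fitting passes (reduce the smoothing
#'   bias on sharp features while keeping gap filling smooth).
#' @param min_coverage minimum sampled-voxel fraction.
#' @return object of class `scan_template` with the completed `rate` array
#'   and geometry.
#' @export
smooth_template <- function(vol, sigma = 1, robust_iters = 2L,
                            refine_iters = 3L, min_coverage = 0.1) {
  stopifnot(inherits(vol, "rate_volume"))
  obs <- vol$dwell > 0 & is.finite(vol$rate)
  if (mean(obs) < min_coverage)
    stopf("smooth_template: only %.1f%% of voxels sampled (need >= %.0f%%)",
          100 * mean(obs), 100 * min_coverage)
  v <- vol$rate
  v[!obs] <- 0
  nconv <- function(x, w, s) {
    num <- gauss_smooth_nd(x * w, rep(s, 3))
    den <- gauss_smooth_nd(w, rep(s, 3))
    smax <- 8 * s + max(dim(x))
    while (any(den < 1e-10) && s < smax) {
      s <- s * 2
      fill <- den < 1e-10
      num[fill] <- gauss_smooth_nd(x * w, rep(s, 3))[fill]
      den[fill] <- gauss_smooth_nd(w, rep(s, 3))[fill]
    }
    num / pmax(den, 1e-12)
  }
  w <- vol$dwell / mean(vol$dwell[obs])
  est <- NULL
  for (it in seq_len(robust_iters + 1L)) {
    est <- nconv(v, w, sigma)
    # iterated back-fitting: re-smooth the residual so observed voxels are
    # approached (quasi-interpolation) without sharpening the gap fill
    for (k in seq_len(refine_iters)) {
      r <- v - est
      r[!obs] <- 0
      est <- est + nconv(r, w, sigma)
    }
    if (it <= robust_iters) {
      r <- abs(vol$rate - est)
      scale <- stats::median(r[obs], na.rm = TRUE) + 1e-12
      wr <- 1 / pmax(r / scale, 1)   # L1-type: downweight large residuals
      wr[!obs] <- 0
      w <- (vol$dwell / mean(vol$dwell[obs])) * wr
    }
  }
  est[est < 0] <- 0
  structure(list(rate = est, origin = vol$origin, spacing = vol$spacing,
                 dims = vol$dims), class = "scan_template")
}

#' Evaluate a template rate field at continuous coordinates
#'
#' @param template a [smooth_template()] result.
#' @param pts n x 3 matrix (um).
#' @param outside value outside the template domain.
#' @return rates (counts/s).
#' @export
template_eval <- function(template, pts, outside = 0) {
  interp_trilinear(template$rate, template$origin, template$spacing,
                   rbind(pts), outside = outside)
}
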