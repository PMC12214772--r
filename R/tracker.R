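#' Tracker configuration
#'
#' Parameters of the closed-loop 3-axis tracker. The beam is scanned in a
#' cylinder of radius `R_scan` about the current position estimate while the
#' TAG lens sweeps `±A_track` axially; photons within `±Z_gate` of the
#' estimated axial position contribute to a center-of-mass position
#' measurement, which a per-axis Kalman filter fuses with the running
#' estimate.
#'
#' @param R_scan cylinder radius (um).
#' @param Z_gate axial gate half-height (um).
#' @param rev_rate cylinder revolutions per second (galvo limit 3000).
#' @param A_track tracking-path TAG half-amplitude (um).
#' @param D responsiveness parameter (um^2/s): the prior variance grows by
#'   `D*dt` between measurements. Larger values weight new measurements more
#'   heavily (faster, noisier tracking). The default was fixed by a
#'   simulation sweep over stride-pulse trajectories.
#' @param stage_period stage re-centering interval (s).
#' @param cycle_period one measurement cycle (s).
#' @param track_power excitation power factor of the tracking beam.
#' @param n_sub axial subdivisions per TAG line in the simulated scan.
#' @param lost_after consecutive zero-photon cycles before tracking is
#'   declared lost.
#' @return object of class `tracker_config`.
#' @export
tracker_config <- function(R_scan = 3, Z_gate = 5, rev_rate = 2857,
                           A_track = 15, D = 2000, stage_period = 0.025,
                           cycle_period = 350e-6, track_power = 5,
                           n_sub = 5L, lost_after = 50L) {
  if (R_scan <= 0 || Z_gate <= 0) stopf("tracker_config: R_scan and Z_gate must be positive")
  if (rev_rate > 3000) stopf("tracker_config: rev_rate exceeds the 3000 rev/s galvo limit")
  if (D < 0 || cycle_period <= 0) stopf("tracker_config: D >= 0 and cycle_period > 0 required")
  structure(list(R_scan = R_scan, Z_gate = Z_gate, rev_rate = rev_rate,
                 A_track = A_track, D = D, stage_period = stage_period,
                 cycle_period = cycle_period, track_power = track_power,
                 n_sub = as.integer(n_sub), lost_after = as.integer(lost_after)),
            class = "tracker_config")
}

#' Center-of-mass position estimate from one cylindrical scan
#'
#' Photons carry the beam position (relative to the scan center) at their
#' emission time. Photons outside the axial gate `|z| <= Z_gate` are
#' discarded; the estimate is the mean of the remaining coordinates with
#' shot-noise errors `sigma_x = sigma_y = R_scan/sqrt(N)` and
#' `sigma_z = Z_gate/sqrt(N)`.
#'
#' @param photons data frame or matrix with columns/cols `x`, `y`, `z`
#'   (um, relative to the scan center).
#' @param cfg a [tracker_config()].
#' @return list of class `track_estimate`: `xyz`, `sigma` (length-3), and
#'   `n_photons`. With zero gated photons, `n_photons` is 0 and `xyz` is
#'   `NA` (a no-measurement signal: the caller holds its state).
#' @export
estimate_position <- function(photons, cfg) {
  stopifnot(inherits(cfg, "tracker_config"))
  m <- as.matrix(as.data.frame(photons)[, c("x", "y", "z")])
  keep <- abs(m[, 3]) <= cfg$Z_gate
  m <- m[keep, , drop = FALSE]
  n <- nrow(m)
  if (n == 0L)
    return(structure(list(xyz = rep(NA_real_, 3), sigma = rep(Inf, 3),
                          n_photons = 0L), class = "track_estimate"))
  structure(list(
    xyz = colMeans(m),
    sigma = c(cfg$R_scan, cfg$R_scan, cfg$Z_gate) / sqrt(n),
    n_photons = n
  ), class = "track_estimate")
}

#' One Kalman update of the tracked position
#'
#' Per axis: the prior variance inflates to `s2p = s2 + D*dt`; the gain is
#' `K = s2p/(s2p + sm^2)`; the position moves `K` of the way to the
#' measurement and the posterior variance is `(1-K)*s2p`. A missing
#' measurement (`est$n_photons == 0` or `est = NULL`) yields the
#' predict-only update (position unchanged, variance inflated).
#'
#' @param state list with `xyz` (length-3 position, um), `var` (length-3
#'   variance, um^2) and `t` (s).
#' @param est a `track_estimate` from [estimate_position()], or `NULL`.
#' @param dt time since the previous update (s).
#' @param D responsiveness parameter (um^2/s).
#' @return updated state.
#' @export
kalman_update <- function(state, est, dt, D) {
  if (dt < 0) stopf("kalman_update: dt must be non-negative")
  s2p <- state$var + D * dt
  if (is.null(est) || est$n_photons == 0L) {
    state$var <- s2p
    state$t <- state$t + dt
    return(state)
  }
  K <- s2p / (s2p + est$sigma^2)
  state$xyz <- (1 - K) * state$xyz + K * est$xyz
  state$var <- (1 - K) * s2p
  state$t <- state$t + dt
  state
}

# beam positions (relative to scan center) for one cylinder cycle
cylinder_points <- function(cfg, f_tag, t0 = 0) {
  n_lines <- max(1L, round(cfg$cycle_period * 2 * f_tag))
  n <- n_lines * cfg$n_sub
  dt <- cfg$cycle_period / n
  tt <- (seq_len(n) - 0.5) * dt
  ang <- 2 * pi * cfg$rev_rate * tt
  phi <- 2 * pi * f_tag * (t0 + tt)
  cbind(x = cfg$R_scan * cos(ang), y = cfg$R_scan * sin(ang),
        z = cfg$A_track * cos(phi), t = t0 + tt, dt = dt)
}

#' Closed-loop tracking of the phantom's reference cell
#'
#' Simulates the full measurement loop: every `cycle_period` the beam scans
#' a cylinder centered on the current estimate, red photons are drawn from
#' the phantom at the beam positions, gated, and averaged, and the Kalman
#' filter absorbs the measurement; the next cylinder is centered on the new
#' estimate. The stage re-centers (discretely) every `stage_period`.
#'
#' @param phantom a [build_phantom()] result.
#' @param cfg a [tracker_config()].
#' @param duration tracking duration (s).
#' @param f_tag TAG frequency (Hz).
#' @param seed integer.
#' @param init_error initial estimate offset (length-3, um).
#' @return data frame of class `track_record`: per cycle `t_s`, estimated
#'   and true positions (`est_*_um`, `true_*_um`), `sigma_um`, `n_photons`,
#'   and `stage_*_um`.
#' @export
closed_loop_track <- function(phantom, cfg, duration, f_tag = 1.9e5,
                              seed = phantom$cfg$seed,
                              init_error = c(0, 0, 0)) {
  stopifnot(inherits(phantom, "phantom"), inherits(cfg, "tracker_config"))
  set.seed(substream_seed(seed, "track"))
  n_cyc <- floor(duration / cfg$cycle_period)
  truth0 <- tracked_cell_path(phantom, 0)
  state <- list(xyz = as.numeric(truth0) + init_error,
                var = rep(cfg$R_scan^2, 3), t = 0)
  stage <- c(0, 0, 0)
  rec <- matrix(NA_real_, n_cyc, 14)
  zero_run <- 0L
  next_stage_t <- cfg$stage_period
  base <- cylinder_points(cfg, f_tag)
  for (i in seq_len(n_cyc)) {
    t0 <- (i - 1) * cfg$cycle_period
    pts_rel <- base
    pts_lab <- cbind(pts_rel[, 1] + state$xyz[1], pts_rel[, 2] + state$xyz[2],
                     pts_rel[, 3] + state$xyz[3])
    st <- blob_state_at(phantom, t0 + cfg$cycle_period / 2)
    near <- which(sqrt((st$centers[, 1] - state$xyz[1])^2 +
                         (st$centers[, 2] - state$xyz[2])^2) <
                    (cfg$R_scan + 6 * phantom$sigma_lateral + 10))
    if (length(near)) {
      stn <- list(centers = st$centers[near, , drop = FALSE],
                  amp_red = st$amp_red[near], amp_green = st$amp_green[near])
      rate <- rate_at_points(phantom, pts_lab, stn,
                             c(red = cfg$track_power, green = 0))$red
    } else rate <- numeric(nrow(pts_lab))
    cnt <- stats::rpois(length(rate), rate * pts_rel[, "dt"])
    tot <- sum(cnt)
    if (tot > 0) {
      keep <- abs(pts_rel[, 3]) <= cfg$Z_gate & cnt > 0
      ngate <- sum(cnt[keep])
      if (ngate > 0) {
        com <- c(sum(pts_rel[keep, 1] * cnt[keep]),
                 sum(pts_rel[keep, 2] * cnt[keep]),
                 sum(pts_rel[keep, 3] * cnt[keep])) / ngate
        est <- structure(list(xyz = state$xyz + com,
                              sigma = c(cfg$R_scan, cfg$R_scan, cfg$Z_gate) /
                                sqrt(ngate),
                              n_photons = ngate), class = "track_estimate")
      } else est <- NULL
    } else est <- NULL
    if (is.null(est)) zero_run <- zero_run + 1L else zero_run <- 0L
    if (zero_run > cfg$lost_after)
      stopf("closed_loop_track: tracking lost (no photons for %d cycles)",
            zero_run)
    state <- kalman_update(state, est, cfg$cycle_period, cfg$D)
    t1 <- i * cfg$cycle_period
    if (t1 >= next_stage_t) {
      # discrete proportional re-centering: the stage absorbs the galvo
      # offset; estimate and truth are kept in lab coordinates
      stage <- state$xyz
      next_stage_t <- next_stage_t + cfg$stage_period
    }
    tr <- tracked_cell_path(phantom, t1)
    rec[i, ] <- c(t1, state$xyz, tr, sqrt(state$var),
                  if (is.null(est)) 0 else est$n_photons, stage)
  }
  out <- as.data.frame(rec)
  names(out) <- c("t_s", "est_x_um", "est_y_um", "est_z_um",
                  "true_x_um", "true_y_um", "true_z_um",
                  "sigma_x_um", "sigma_y_um", "sigma_z_um",
                  "n_photons", "stage_x_um", "stage_y_um", "stage_z_um")
  class(out) <- c("track_record", "data.frame")
  out
}
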