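#' Phantom configuration
#'
#' Parameters of the synthetic crawling nerve-cord phantom: a ladder of
#' segmentally repeated fluorescent cells (a midline process column plus two
#' lateral cell-body columns), co-expressing a stable red fluorophore and a
#' green activity reporter, crawling with stride-locked velocity pulses,
#' optionally rotating and bending, and carrying a phase-locked traveling
#' activity wave on the behaviorally gated cell class.
#'
#' The velocity profile within a stride is
#' `v(t) = peak_speed * (duty + (1 - duty) * cos(theta))` with `theta`
#' advancing `2*pi` per `stride_period`; `duty` sets the forward bias (the
#' mean speed is `peak_speed * duty`, and the brain recoils slightly between
#' pulses, as tracked brains do). The phantom's true stride phase
#' `phi_true` is the instantaneous (analytic-signal) phase of this velocity
#' oscillation, available in closed form:
#' `phi_true = atan2(sin(theta), r + cos(theta))` with
#' `r = duty/(1 - duty)`.
#'
#' @param n_segments number of ladder segments.
#' @param segment_spacing spacing between segments along the body axis (um).
#' @param cell_radius Gaussian radius (sigma) of a labeled cell (um).
#' @param lateral_offset distance of the lateral cell-body columns from the
#'   midline (um).
#' @param red_rate peak red photon rate at focus, at unit excitation power
#'   (counts/s).
#' @param green_base peak unmodulated green photon rate at focus (counts/s).
#' @param wave_amplitude relative modulation `m` of the activity wave
#'   (0 to 1).
#' @param wave_vector spatial wave number `k` along the body axis (rad/um);
#'   default one full cycle across the ladder.
#' @param forward_class,backward_class which cell class (`"medial"` or
#'   `"lateral"`) carries the wave during forward / backward bouts.
#' @param psf_sigma_lateral,psf_sigma_axial Gaussian PSF sigmas (um).
#' @param background_rate peak photon rate of an off-target autofluorescent
#'   rod (counts/s, both channels).
#' @param tracked_rate_mult brightness multiplier of the tracked reference
#'   cell relative to `red_rate`.
#' @param stride_period stride duration (s).
#' @param peak_speed peak crawl speed (um/s).
#' @param duty forward bias of the velocity pulse (0.5 would never recoil).
#' @param rotation_amplitude,rotation_period slow in-plane rotation (rad, s).
#' @param tilt_amplitude out-of-plane tilt amplitude (rad).
#' @param deform_amplitude peak displacement of the smooth non-rigid bending
#'   field (um); 0 disables deformation.
#' @param deform_grid control-grid dimensions (x, y, z) of the bending
#'   field's B-spline parameterization.
#' @param bouts data frame with columns `state` ("forward", "backward" or
#'   "other"), `start`, `end` (s); default one forward bout of 6 strides.
#' @param origin_um lab-frame position of the body center at `t = 0`
#'   (length 3); the whole trajectory shifts with it.
#' @param seed integer seed for photon emission.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(n_segments = 8, segment_spacing = 8,
                           cell_radius = 2, lateral_offset = 6,
                           red_rate = 2e6, green_base = 1.5e6,
                           wave_amplitude = 0.8, wave_vector = NULL,
                           forward_class = "medial",
                           backward_class = "lateral",
                           psf_sigma_lateral = 0.5, psf_sigma_axial = 1.5,
                           background_rate = 2e5, tracked_rate_mult = 4,
                           stride_period = 1.5, peak_speed = 800, duty = 0.15,
                           rotation_amplitude = 0, rotation_period = 4,
                           tilt_amplitude = 0,
                           deform_amplitude = 0, deform_grid = c(4, 3, 1),
                           bouts = NULL, origin_um = c(0, 0, 0), seed = 1L) {
  if (n_segments < 1) stopf("phantom_config: need at least one segment")
  if (cell_radius <= 0) stopf("phantom_config: cell_radius must be positive")
  if (min(red_rate, green_base, background_rate) < 0)
    stopf("phantom_config: rates must be non-negative")
  if (wave_amplitude < 0 || wave_amplitude > 1)
    stopf("phantom_config: wave_amplitude must lie in [0, 1]")
  if (psf_sigma_lateral <= 0 || psf_sigma_axial <= 0)
    stopf("phantom_config: PSF sigmas must be positive")
  if (duty <= 0 || duty >= 0.5)
    stopf("phantom_config: duty must lie in (0, 0.5) so the phase winds")
  if (segment_spacing <= 2 * cell_radius * 0.5 && n_segments > 1 &&
      segment_spacing <= 0)
    stopf("phantom_config: degenerate segment spacing")
  body_len <- (n_segments - 1) * segment_spacing
  if (is.null(wave_vector))
    wave_vector <- if (body_len > 0) 2 * pi / (body_len + segment_spacing)
      else 0
  if (is.null(bouts))
    bouts <- data.frame(state = "forward", start = 0, end = 6 * stride_period)
  stopifnot(all(c("state", "start", "end") %in% names(bouts)))
  structure(list(
    n_segments = n_segments, segment_spacing = segment_spacing,
    cell_radius = cell_radius, lateral_offset = lateral_offset,
    red_rate = red_rate, green_base = green_base,
    wave_amplitude = wave_amplitude, wave_vector = wave_vector,
    forward_class = forward_class, backward_class = backward_class,
    psf_sigma_lateral = psf_sigma_lateral, psf_sigma_axial = psf_sigma_axial,
    background_rate = background_rate, tracked_rate_mult = tracked_rate_mult,
    stride_period = stride_period, peak_speed = peak_speed, duty = duty,
    rotation_amplitude = rotation_amplitude,
    rotation_period = rotation_period, tilt_amplitude = tilt_amplitude,
    deform_amplitude = deform_amplitude, deform_grid = deform_grid,
    bouts = bouts, origin_um = origin_um, seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Build the static phantom
#'
#' Lays out the fluorophore blob fields in body coordinates (body axis = x,
#' origin at the ladder center). Red and green densities share identical
#' spatial support (co-expression); each blob's effective Gaussian width is
#' the cell radius convolved with the PSF. The tracked reference cell sits
#' anterior-lateral of the ladder; an autofluorescent background rod runs
#' alongside the body.
#'
#' @param cfg a [phantom_config()].
#' @return object of class `phantom`: the blob table, the tracked-cell
#'   index, and the (deterministic) deformation parameterization.
#' @export
build_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  sp <- cfg$segment_spacing
  xs <- (seq_len(cfg$n_segments) - (cfg$n_segments + 1) / 2) * sp
  blobs <- rbind(
    data.frame(x = xs, y = 0, z = 0, class = "medial"),
    data.frame(x = rep(xs, 2), y = rep(c(-1, 1), each = cfg$n_segments) *
                 cfg$lateral_offset, z = 0, class = "lateral")
  )
  blobs$amp_red <- cfg$red_rate
  blobs$amp_green <- cfg$green_base
  # tracked reference cell: bright, just off the ladder near mid-body (the
  # imaged volume is centered on it); one-sided, so together with the
  # background rod it breaks the ladder's in-plane symmetry for rigid
  # registration
  trk <- data.frame(x = sp / 2, y = cfg$lateral_offset + 6, z = 0,
                    class = "tracked",
                    amp_red = cfg$red_rate * cfg$tracked_rate_mult,
                    amp_green = cfg$green_base)
  bg <- if (cfg$background_rate > 0) {
    nb <- max(3L, cfg$n_segments %/% 2L)
    data.frame(x = seq(min(xs), max(xs), length.out = nb),
               y = -(cfg$lateral_offset + 8), z = -6, class = "background",
               amp_red = cfg$background_rate,
               amp_green = cfg$background_rate)
  } else NULL
  blobs <- rbind(blobs, trk, bg)
  blobs$s <- blobs$x - min(xs)   # body-axis coordinate, 0 at posterior end
  sig_lat <- sqrt(cfg$cell_radius^2 + cfg$psf_sigma_lateral^2)
  sig_ax <- sqrt(cfg$cell_radius^2 + cfg$psf_sigma_axial^2)
  deform <- NULL
  if (cfg$deform_amplitude > 0) {
    span_x <- diff(range(blobs$x)) + 4 * sig_lat
    span_y <- diff(range(blobs$y)) + 4 * sig_lat
    deform <- ffd_field(
      origin = c(min(blobs$x) - 2 * sig_lat, min(blobs$y) - 2 * sig_lat, -12),
      spacing = c(span_x / max(1, cfg$deform_grid[1] - 1),
                  span_y / max(1, cfg$deform_grid[2] - 1), 24),
      dims = cfg$deform_grid)
    # smooth in-plane bend: y-displacement varies along x
    g <- deform$grid
    cx <- seq(-1, 1, length.out = dim(g)[1])
    for (i in seq_len(dim(g)[1]))
      g[i, , , 2] <- cfg$deform_amplitude * sin(pi / 2 * cx[i])
    deform$grid <- g
  }
  structure(list(
    cfg = cfg, blobs = blobs, tracked = which(blobs$class == "tracked"),
    sigma_lateral = sig_lat, sigma_axial = sig_ax,
    deform = deform, body_length = diff(range(xs))
  ), class = "phantom")
}

# behavior state at times t: "forward", "backward" or "other"
bout_state <- function(cfg, t) {
  st <- rep("other", length(t))
  for (i in seq_len(nrow(cfg$bouts))) {
    sel <- t >= cfg$bouts$start[i] & t < cfg$bouts$end[i]
    st[sel] <- cfg$bouts$state[i]
  }
  st
}

#' True stride phase of the phantom
#'
#' The instantaneous (analytic-signal) phase of the phantom's velocity
#' oscillation, in closed form; 0 at peak in-travel-direction speed,
#' advancing `2*pi` per stride, defined within bouts (0 elsewhere).
#'
#' @param phantom a [build_phantom()] result (or a `phantom_config`).
#' @param t times (s).
#' @return phase in `[0, 2*pi)`.
#' @export
phi_true_at <- function(phantom, t) {
  cfg <- if (inherits(phantom, "phantom")) phantom$cfg else phantom
  r <- cfg$duty / (1 - cfg$duty)
  phi <- rep(0, length(t))
  for (i in seq_len(nrow(cfg$bouts))) {
    sel <- t >= cfg$bouts$start[i] & t < cfg$bouts$end[i]
    if (!any(sel) || cfg$bouts$state[i] == "other") next
    th <- 2 * pi * (t[sel] - cfg$bouts$start[i]) / cfg$stride_period
    phi[sel] <- atan2(sin(th), r + cos(th)) %% (2 * pi)
  }
  phi
}

# signed forward speed (um/s, along heading) at times t
forward_speed_at <- function(cfg, t) {
  v <- rep(0, length(t))
  for (i in seq_len(nrow(cfg$bouts))) {
    sel <- t >= cfg$bouts$start[i] & t < cfg$bouts$end[i]
    if (!any(sel)) next
    st <- cfg$bouts$state[i]
    if (st == "other") next
    th <- 2 * pi * (t[sel] - cfg$bouts$start[i]) / cfg$stride_period
    pulse <- cfg$peak_speed * (cfg$duty + (1 - cfg$duty) * cos(th))
    v[sel] <- if (st == "forward") pulse else -pulse
  }
  v
}

# displacement along heading (um): closed-form integral of forward_speed_at
displacement_at <- function(cfg, t) {
  d <- rep(0, length(t))
  T <- cfg$stride_period
  for (i in seq_len(nrow(cfg$bouts))) {
    st <- cfg$bouts$state[i]
    if (st == "other") next
    sgn <- if (st == "forward") 1 else -1
    t0 <- cfg$bouts$start[i]; t1 <- cfg$bouts$end[i]
    te <- pmin(pmax(t, t0), t1) - t0
    th <- 2 * pi * te / T
    d <- d + sgn * cfg$peak_speed *
      (cfg$duty * te + (1 - cfg$duty) * T / (2 * pi) * sin(th))
  }
  d
}

#' Ground-truth pose of the phantom
#'
#' @param phantom a `phantom`.
#' @param t times (s), vectorized.
#' @return list with `t`, `translation` (n x 3, um), `angle` (in-plane, rad),
#'   `tilt` (n x 2, rad), `state`, `phi_true`, `v_fwd` (um/s) and `heading`
#'   (n x 2 unit vectors).
#' @export
pose_at <- function(phantom, t) {
  stopifnot(inherits(phantom, "phantom"))
  cfg <- phantom$cfg
  disp <- displacement_at(cfg, t)
  ang <- cfg$rotation_amplitude * sin(2 * pi * t / cfg$rotation_period)
  tilt <- cbind(cfg$tilt_amplitude * sin(2 * pi * t / cfg$rotation_period),
                cfg$tilt_amplitude * cos(2 * pi * t / cfg$rotation_period))
  heading <- cbind(cos(ang), sin(ang))
  list(t = t,
       translation = cbind(disp + cfg$origin_um[1], cfg$origin_um[2],
                           cfg$origin_um[3]),
       angle = ang, tilt = tilt,
       state = bout_state(cfg, t),
       phi_true = phi_true_at(phantom, t),
       v_fwd = forward_speed_at(cfg, t),
       heading = heading)
}

#' Activity multiplier of the green channel
#'
#' During forward bouts the forward-gated cell class carries a traveling
#' plane wave, `gain = 1 + m*cos(k*s - phi_true(t))` (s = body-axis
#' coordinate, posterior = 0), so anterior cells peak later in the cycle
#' than posterior ones; during backward bouts the backward class carries the
#' reversed wave `1 + m*cos(k*s + phi_true(t))`. The inactive class, the
#' tracked cell and the background are unmodulated.
#'
#' @param phantom a `phantom`.
#' @param s body-axis coordinate(s) of the queried point(s) (um, posterior
#'   end = 0).
#' @param t time (scalar, s).
#' @param class cell class of the queried point(s) (`"medial"`,
#'   `"lateral"`, `"tracked"`, `"background"`).
#' @return dimensionless multiplier(s).
#' @export
activity_at <- function(phantom, s, t, class = "medial") {
  stopifnot(inherits(phantom, "phantom"), length(t) == 1L)
  cfg <- phantom$cfg
  state <- bout_state(cfg, t)
  gain <- rep(1, length(s))
  if (cfg$wave_amplitude == 0 || state == "other") return(gain)
  phi <- phi_true_at(phantom, t)
  cls <- rep_len(class, length(s))
  if (state == "forward") {
    on <- cls == cfg$forward_class
    gain[on] <- 1 + cfg$wave_amplitude * cos(cfg$wave_vector * s[on] - phi)
  } else {
    on <- cls == cfg$backward_class
    gain[on] <- 1 + cfg$wave_amplitude * cos(cfg$wave_vector * s[on] + phi)
  }
  gain
}

# world-frame blob centers at (scalar) time t, with per-blob green gains.
# Deformation is applied by exact fixed-point inversion of y + u(y) = c so
# that the deformed density is the template density pulled through
# (id + u)^-1, matching what non-rigid registration estimates.
blob_state_at <- function(phantom, t) {
  cfg <- phantom$cfg
  b <- phantom$blobs
  body <- cbind(b$x, b$y, b$z)
  if (!is.null(phantom$deform)) {
    y <- body
    for (it in 1:8) {
      u <- ffd_displacement(phantom$deform, y)
      ynew <- body - u
      if (max(abs(ynew - y)) < 1e-6) { y <- ynew; break }
      y <- ynew
    }
    body <- y
  }
  po <- pose_at(phantom, t)
  ca <- cos(po$angle[1]); sa <- sin(po$angle[1])
  tx <- po$tilt[1, 1]; ty <- po$tilt[1, 2]
  # in-plane rotation, then small out-of-plane tilts about x and y
  xw <- ca * body[, 1] - sa * body[, 2]
  yw <- sa * body[, 1] + ca * body[, 2]
  zw <- body[, 3]
  if (tx != 0 || ty != 0) {
    y2 <- cos(tx) * yw - sin(tx) * zw; z2 <- sin(tx) * yw + cos(tx) * zw
    x3 <- cos(ty) * xw + sin(ty) * z2; z3 <- -sin(ty) * xw + cos(ty) * z2
    xw <- x3; yw <- y2; zw <- z3
  }
  centers <- cbind(xw + po$translation[1, 1], yw + po$translation[1, 2],
                   zw + po$translation[1, 3])
  gain <- activity_at(phantom, b$s, t, b$class)
  list(centers = centers, amp_red = b$amp_red,
       amp_green = b$amp_green * gain)
}

# photon rate (counts/s) of each channel at lab-frame points, given a blob
# state; returns list(red, green)
rate_at_points <- function(phantom, pts, state, powers = c(red = 1, green = 1)) {
  dx2 <- outer(pts[, 1], state$centers[, 1], "-")^2 +
    outer(pts[, 2], state$centers[, 2], "-")^2
  dz2 <- outer(pts[, 3], state$centers[, 3], "-")^2
  G <- exp(-dx2 / (2 * phantom$sigma_lateral^2) -
             dz2 / (2 * phantom$sigma_axial^2))
  list(red = as.numeric(G %*% state$amp_red) * powers[["red"]],
       green = as.numeric(G %*% state$amp_green) * powers[["green"]])
}

#' True lab-frame position of the tracked reference cell
#'
#' @param phantom a `phantom`.
#' @param t times (s).
#' @return n x 3 matrix (um).
#' @export
tracked_cell_path <- function(phantom, t) {
  out <- matrix(0, length(t), 3)
  for (i in seq_along(t)) {
    st <- blob_state_at(phantom, t[i])
    out[i, ] <- st$centers[phantom$tracked, ]
  }
  out
}

#' Emit photons along an imaging scan
#'
#' Simulates inhomogeneous Poisson photon emission while the imaging beam
#' follows the recorded scan samples. Each axial line is subdivided into
#' `n_sub` TAG-phase bins; within a bin the rate is held constant (the bin
#' spans a fraction of the 2.6 us line), and photon counts are drawn
#' per bin and channel. The lab-frame focal position of a bin is the line's
#' galvo position plus the axial excursion `A_tag*cos(phi)` about the
#' tracked z estimate. Arrival phases within the (multiplexed) laser period
#' are drawn around each path's half-period window with Gaussian jitter.
#'
#' @param phantom a `phantom`.
#' @param samples a scan-sample table from [make_scan_samples()].
#' @param scan_cfg the [scan_config()] used to drive the scan.
#' @param powers named numeric, excitation power factors `c(red=, green=)`.
#' @param n_sub TAG-phase subdivisions per axial line; the default keeps the
#'   axial rate-evaluation step below ~4 um at a 20 um half-amplitude.
#'   Photon times are drawn uniformly within a sub-bin, so located axial
#'   positions remain continuous.
#' @param seed integer; reproducible streams.
#' @param pose_dt pose update interval (s) for the moving phantom.
#' @param laser_period_ns,demux_offset_ns,jitter_ns temporal-multiplexing
#'   timing (70 MHz laser; imaging and tracking pulse trains displaced by a
#'   half cycle).
#' @return `data.frame` of photon events: `t_s`, `channel`,
#'   `arrival_phase_ns`, `path_true`.
#' @export
emit_photons <- function(phantom, samples, scan_cfg,
                         powers = c(red = 1, green = 1), n_sub = 16L,
                         seed = phantom$cfg$seed, pose_dt = 5e-4,
                         laser_period_ns = 1e9 / 7e7,
                         demux_offset_ns = 7.1, jitter_ns = 0.5) {
  stopifnot(inherits(phantom, "phantom"), inherits(scan_cfg, "scan_config"))
  if (any(powers < 0)) stopf("emit_photons: powers must be non-negative")
  n_sub <- as.integer(n_sub)
  set.seed(substream_seed(seed, "emit"))
  nline <- nrow(samples)
  f_tag <- scan_cfg$f_tag
  dt_sub <- 1 / (2 * f_tag * n_sub)
  sub_off <- ((seq_len(n_sub) - 0.5) / n_sub - 0.5) * pi   # phase offsets
  chunks <- split(seq_len(nline), ceiling(seq_len(nline) / 50000L))
  out <- vector("list", length(chunks))
  for (ci in seq_along(chunks)) {
    rows <- chunks[[ci]]
    sm <- samples[rows, ]
    np <- length(rows) * n_sub
    t_pt <- rep(sm$t_s, each = n_sub) +
      rep(sub_off, length(rows)) / (2 * pi * f_tag)
    phi_pt <- rep(sm$phi_rad, each = n_sub) + rep(sub_off, length(rows))
    x_pt <- rep(sm$x_galvo_um, each = n_sub)
    y_pt <- rep(sm$y_galvo_um, each = n_sub)
    z_pt <- scan_cfg$A_tag * cos(phi_pt) + rep(sm$z_tracker_um, each = n_sub)
    pose_id <- floor(t_pt / pose_dt)
    red <- numeric(np); green <- numeric(np)
    for (pid in unique(pose_id)) {
      sel <- pose_id == pid
      st <- blob_state_at(phantom, (pid + 0.5) * pose_dt)
      r <- rate_at_points(phantom, cbind(x_pt[sel], y_pt[sel], z_pt[sel]),
                          st, powers)
      red[sel] <- r$red; green[sel] <- r$green
    }
    cnt_r <- stats::rpois(np, red * dt_sub)
    cnt_g <- stats::rpois(np, green * dt_sub)
    ir <- rep.int(seq_len(np), cnt_r)
    ig <- rep.int(seq_len(np), cnt_g)
    if (length(ir) + length(ig) == 0L) { out[[ci]] <- NULL; next }
    tj <- c(t_pt[ir], t_pt[ig]) +
      (stats::runif(length(ir) + length(ig)) - 0.5) * dt_sub
    ev <- data.frame(
      t_s = tj,
      channel = rep(c("red", "green"), c(length(ir), length(ig))),
      stringsAsFactors = FALSE)
    ev$arrival_phase_ns <- (laser_period_ns / 4 +
      stats::rnorm(nrow(ev), 0, jitter_ns)) %% laser_period_ns
    ev$path_true <- "imaging"
    out[[ci]] <- ev
  }
  ev <- do.call(rbind, out)
  if (is.null(ev))
    ev <- data.frame(t_s = numeric(0), channel = character(0),
                     arrival_phase_ns = numeric(0), path_true = character(0))
  ev[order(ev$t_s), , drop = FALSE]
}

#' Ground-truth behavior tables
#'
#' @param phantom a `phantom`.
#' @return list with `bouts` (data frame), `strides` (data frame of stride
#'   start/end times nested in bouts, `state` per stride) and the closed
#'   form `phi_true` accessor.
#' @export
behavior_truth <- function(phantom) {
  cfg <- phantom$cfg
  strides <- do.call(rbind, lapply(seq_len(nrow(cfg$bouts)), function(i) {
    if (cfg$bouts$state[i] == "other") return(NULL)
    t0 <- cfg$bouts$start[i]; t1 <- cfg$bouts$end[i]
    starts <- seq(t0, t1 - cfg$stride_period + 1e-9, by = cfg$stride_period)
    if (!length(starts)) return(NULL)
    data.frame(start = starts, end = starts + cfg$stride_period,
               state = cfg$bouts$state[i], bout = i)
  }))
  list(bouts = cfg$bouts, strides = strides,
       phi_true = function(t) phi_true_at(phantom, t))
}
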