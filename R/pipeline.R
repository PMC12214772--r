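#' Demonstration run configuration
#'
#' A desk-scale end-to-end configuration: an 8-segment phantom crawling
#' through six strides inside an 80 x 40 um field, imaged with a Pong scan
#' while the tracker follows the reference cell. Sub-configurations can be
#' overridden by passing replacement objects.
#'
#' @param seed integer master seed; per-stage streams are derived from it.
#' @param scan,phantom,tracker optional replacement configs.
#' @param duration recording duration (s); default the end of the last
#'   bout.
#' @param frame_s rigid-registration frame window (s); default the time to
#'   oversample the field 3.125-fold at 1 um^-2 pixel density.
#' @param movie_bin_s movie time bin (s); default half the characteristic
#'   raster time.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, scan = NULL, phantom = NULL,
                       tracker = NULL, duration = NULL, frame_s = NULL,
                       movie_bin_s = NULL) {
  if (is.null(scan))
    scan <- scan_config(a_x = 80, r_xy = 2, tau_min = 5.2e-6, dx = 1,
                        f_max = 1200, A_tag = 20)
  if (is.null(phantom))
    phantom <- phantom_config(seed = seed)
  if (is.null(tracker)) tracker <- tracker_config()
  if (is.null(duration)) duration <- max(phantom$bouts$end)
  if (is.null(frame_s))
    frame_s <- 3.125 * (scan$a_x * scan$a_x / scan$r_xy) * scan$tau_min
  if (is.null(movie_bin_s))
    movie_bin_s <- raster_characteristic_time(scan) / 2
  structure(list(seed = as.integer(seed), scan = scan, phantom = phantom,
                 tracker = tracker, duration = duration, frame_s = frame_s,
                 movie_bin_s = movie_bin_s),
            class = "run_config")
}

#' Run the end-to-end synthetic demonstration
#'
#' Simulate -> track -> reconstruct -> register -> strides -> waves on the
#' synthetic phantom, with no external input. Returns all intermediate
#' products; optionally writes the standard file bundle.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (`NULL` to skip writing).
#' @param nonrigid run the non-rigid registration stage (slower; useful
#'   when the phantom is configured with deformation).
#' @param verbose print stage progress.
#' @return list of class `run_result`: track record, event tables, the
#'   template, per-frame corrections, movie, phase clock, stride table,
#'   stride cubes, wave decomposition and fit, VOI traces, QC list.
#' @export
run_demo <- function(cfg = run_config(), out_dir = NULL, nonrigid = FALSE,
                     verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- Sys.time()
  qc <- list(seed = cfg$seed, config_hash = config_hash(cfg),
             r_version = as.character(getRversion()))
  ph <- build_phantom(cfg$phantom)
  truth <- behavior_truth(ph)

  say("tracking (%.1f s of %.0f us cycles)...", cfg$duration,
      cfg$tracker$cycle_period * 1e6)
  rec <- closed_loop_track(ph, cfg$tracker, cfg$duration,
                           f_tag = cfg$scan$f_tag, seed = cfg$seed)
  est <- data.frame(t_s = rec$t_s, x_um = rec$est_x_um, y_um = rec$est_y_um,
                    z_um = rec$est_z_um)
  qc$track_rms_um <- sqrt(mean((rec$est_x_um - rec$true_x_um)^2 +
                                 (rec$est_y_um - rec$true_y_um)^2 +
                                 (rec$est_z_um - rec$true_z_um)^2))

  say("imaging scan + photon emission...")
  traj <- pong_trajectory(cfg$scan, cfg$duration)
  samples <- make_scan_samples(traj, est)
  events <- emit_photons(ph, samples, cfg$scan, seed = cfg$seed)
  events$path <- demultiplex(events$arrival_phase_ns)
  qc$demux_misassigned <- mean(events$path != events$path_true)
  events <- events[events$path == "imaging", , drop = FALSE]
  red <- locate_events(events[events$channel == "red", , drop = FALSE],
                       samples, cfg$scan)
  green <- locate_events(events[events$channel == "green", , drop = FALSE],
                         samples, cfg$scan)
  qc$n_red <- nrow(red); qc$n_green <- nrow(green)

  say("template + registration (%d red / %d green photons)...",
      nrow(red), nrow(green))
  geom <- make_geometry(c(-cfg$scan$a_x / 2, cfg$scan$a_x / 2,
                          -cfg$scan$a_x / (2 * cfg$scan$r_xy),
                          cfg$scan$a_x / (2 * cfg$scan$r_xy),
                          -cfg$scan$A_tag, cfg$scan$A_tag))
  vol_red <- assemble_volume(red, samples, cfg$scan, geom)
  template <- smooth_template(vol_red)
  n_frames <- max(1L, floor(cfg$duration / cfg$frame_s))
  edges <- seq(0, by = cfg$frame_s, length.out = n_frames + 1L)
  frames_red <- lapply(seq_len(n_frames), function(i)
    red[red$t_s >= edges[i] & red$t_s < edges[i + 1], , drop = FALSE])
  tfs <- register_sequence(frames_red, template, continuity_weight = 0.01,
                           sweeps = 1L)
  loc_s <- emission_location(samples, cfg$scan)
  line_t <- 1 / (2 * cfg$scan$f_tag)
  thin <- 4L   # line thinning for the intensity integral (dt scaled up)
  corr_red <- list(); corr_green <- list()
  alphas <- vector("list", n_frames)
  ffds <- vector("list", n_frames)
  dropped <- 0L
  for (i in seq_len(n_frames)) {
    fr <- frames_red[[i]]
    fg <- green[green$t_s >= edges[i] & green$t_s < edges[i + 1], ,
                drop = FALSE]
    sm <- samples$t_s >= edges[i] & samples$t_s < edges[i + 1]
    ffd <- NULL
    if (nonrigid) {
      fr_reg <- fr
      p <- rigid_apply(tfs[[i]], as.matrix(fr[, c("x_um", "y_um", "z_um")]))
      fr_reg$x_um <- p[, 1]; fr_reg$y_um <- p[, 2]; fr_reg$z_um <- p[, 3]
      sm_reg <- samples[sm, , drop = FALSE]
      vol_f <- assemble_volume(fr_reg, sm_reg, cfg$scan, geom)
      ffd <- nonrigid_register(vol_f, template)
    }
    sm_idx <- which(sm)
    sm_idx <- sm_idx[seq(1L, length(sm_idx), by = thin)]
    path_pts <- rigid_apply(tfs[[i]], as.matrix(loc_s[sm_idx, ]))
    if (!is.null(ffd)) path_pts <- path_pts + ffd_displacement(ffd, path_pts)
    ph_pts <- rigid_apply(tfs[[i]], as.matrix(fr[, c("x_um", "y_um", "z_um")]))
    if (!is.null(ffd)) ph_pts <- ph_pts + ffd_displacement(ffd, ph_pts)
    alpha <- intensity_correct(ph_pts, path_pts, line_t * thin, template)
    cr <- apply_corrections(fr, fg, tfs[[i]], ffd, alpha, template)
    dropped <- dropped + cr$qc$dropped_red + cr$qc$dropped_green
    corr_red[[i]] <- cr$red
    corr_green[[i]] <- cr$green
    alphas[[i]] <- alpha
    ffds[[i]] <- ffd
  }
  red_c <- do.call(rbind, corr_red)
  green_c <- do.call(rbind, corr_green)
  qc$dropped_out_of_domain <- dropped

  say("movie + behavior...")
  # movie voxels are 2x the template grid to keep the 4D arrays light
  geom_mv <- make_geometry(c(-cfg$scan$a_x / 2, cfg$scan$a_x / 2,
                             -cfg$scan$a_x / (2 * cfg$scan$r_xy),
                             cfg$scan$a_x / (2 * cfg$scan$r_xy),
                             -cfg$scan$A_tag, cfg$scan$A_tag),
                          spacing = c(2, 2, 4))
  movie <- assemble_movie(rbind(red_c, green_c), samples, cfg$scan, geom_mv,
                          time_bin = cfg$movie_bin_s)
  track_df <- data.frame(t_s = rec$t_s, x_um = rec$est_x_um,
                         y_um = rec$est_y_um)
  po <- pose_at(ph, rec$t_s)
  heading <- data.frame(t_s = rec$t_s, hx = po$heading[, 1],
                        hy = po$heading[, 2])
  vel <- forward_velocity(track_df, heading)
  fwd <- cfg$phantom$bouts[cfg$phantom$bouts$state == "forward", ,
                           drop = FALSE]
  vb <- vel[vel$t_s >= fwd$start[1] & vel$t_s <= fwd$end[1], , drop = FALSE]
  clock <- hilbert_phase(vb, "forward")
  strides <- segment_strides(clock)
  warp <- warp_align(clock, vb, strides)
  clock_r <- warp$clock

  say("stride-aligned waves...")
  geom2 <- make_geometry(c(-cfg$scan$a_x / 2, cfg$scan$a_x / 2,
                           -cfg$scan$a_x / (2 * cfg$scan$r_xy),
                           cfg$scan$a_x / (2 * cfg$scan$r_xy), -1, 1),
                         spacing = c(2, 2, 2))
  cube_g <- stride_average(green_c, samples, cfg$scan, clock_r, strides,
                           geometry = geom2)
  cube_r <- stride_average(red_c, samples, cfg$scan, clock_r, strides,
                           geometry = geom2)
  decomp <- wave_pca(cube_g)
  fit <- wave_variance_explained(cube_g, decomp)
  qc$wave_variance_explained <- fit$variance_explained

  # VOIs on the medial (forward-gated) cells, template coordinates
  trk_body <- ph$blobs[ph$tracked, ]
  med <- ph$blobs[ph$blobs$class == "medial", ]
  vois <- data.frame(x_um = med$x - trk_body$x, y_um = med$y - trk_body$y,
                     z_um = med$z - trk_body$z, r_um = 4,
                     name = sprintf("seg%02d", seq_len(nrow(med))))
  traces <- voi_ratio(movie, vois)

  res <- structure(list(
    cfg = cfg, phantom = ph, truth = truth, track = rec,
    red = red_c, green = green_c, samples = samples, template = template,
    transforms = tfs, alphas = alphas, ffds = ffds, movie = movie,
    velocity = vel, clock = clock_r, strides = strides, warp = warp,
    cube_green = cube_g, cube_red = cube_r, decomposition = decomp,
    wave_fit = fit, vois = vois, traces = traces, qc = qc
  ), class = "run_result")
  if (!is.null(out_dir)) write_run(res, out_dir)
  say("done in %.1f min", as.numeric(difftime(Sys.time(), t_start,
                                              units = "mins")))
  res
}

#' Write the standard output bundle of a run
#'
#' @param res a [run_demo()] result.
#' @param out_dir directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(res, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir))
      stopf("write_run: cannot create output directory '%s'", out_dir)
  }
  p <- function(f) file.path(out_dir, f)
  utils::write.csv(res$track, p("track_record.csv"), row.names = FALSE)
  utils::write.csv(res$red, p("events_red.csv"), row.names = FALSE)
  utils::write.csv(res$green, p("events_green.csv"), row.names = FALSE)
  utils::write.csv(res$strides, p("strides.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(res$clock), p("phase_clock.csv"),
                   row.names = FALSE)
  utils::write.csv(res$traces, p("voi_traces.csv"), row.names = FALSE)
  utils::write.csv(res$warp$template, p("stride_template.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    seed = res$qc$seed, config_hash = res$qc$config_hash,
    r_version = res$qc$r_version, track_rms_um = res$qc$track_rms_um,
    demux_misassigned = res$qc$demux_misassigned,
    n_red = res$qc$n_red, n_green = res$qc$n_green,
    dropped_out_of_domain = res$qc$dropped_out_of_domain,
    wave = list(variance_explained = res$wave_fit$variance_explained,
                k = res$wave_fit$k, phi0 = res$wave_fit$phi0)
  ), p("qc.json"), auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(list(seed = res$cfg$seed,
                        scan = unclass(res$cfg$scan),
                        phantom = unclass(res$cfg$phantom)[
                          setdiff(names(unclass(res$cfg$phantom)), "bouts")],
                        tracker = unclass(res$cfg$tracker)),
                   p("config.yaml"))
  invisible(out_dir)
}

table_schemas <- list(
  events = list(cols = c("t_s", "channel"), time = "t_s",
                channel_values = c("red", "green")),
  samples = list(cols = c("t_s", "x_galvo_um", "y_galvo_um", "x_tracker_um",
                          "y_tracker_um", "phi_rad", "z_off_um"),
                 time = "t_s"),
  track = list(cols = c("t_s", "est_x_um", "est_y_um", "est_z_um"),
               time = "t_s"),
  trace = list(cols = c("voi", "t_s", "ratio_norm"), time = NULL)
)

#' Validate a table file against the package schemas
#'
#' Checks column presence, finiteness of numeric columns, strictly
#' increasing time, and channel labels, returning a machine-readable
#' report.
#'
#' @param path CSV file.
#' @param kind one of `"events"`, `"samples"`, `"track"`, `"trace"`.
#' @return list of class `schema_report` with `valid` and a character
#'   vector of `violations`.
#' @export
validate_tables <- function(path, kind = c("events", "samples", "track",
                                           "trace")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("validate_tables: no such file '%s'", path)
  sc <- table_schemas[[kind]]
  df <- utils::read.csv(path)
  viol <- character(0)
  miss <- setdiff(sc$cols, names(df))
  if (length(miss))
    viol <- c(viol, sprintf("missing column '%s'", miss))
  if (!is.null(sc$time) && sc$time %in% names(df)) {
    tv <- df[[sc$time]]
    if (anyNA(tv) || any(!is.finite(tv)))
      viol <- c(viol, sprintf("non-finite values in '%s'", sc$time))
    else if (is.unsorted(tv, strictly = FALSE))
      viol <- c(viol, sprintf("'%s' is not monotone non-decreasing",
                              sc$time))
  }
  if (!is.null(sc$channel_values) && "channel" %in% names(df)) {
    bad <- setdiff(unique(df$channel), sc$channel_values)
    if (length(bad))
      viol <- c(viol, sprintf("unknown channel '%s'", bad))
  }
  structure(list(valid = length(viol) == 0L, kind = kind,
                 n_rows = nrow(df), violations = viol),
            class = "schema_report")
}

#' @export
print.schema_report <- function(x, ...) {
  cat(sprintf("schema_report [%s]: %s (%d rows)\n", x$kind,
              if (x$valid) "valid" else "INVALID", x$n_rows))
  for (v in x$violations) cat("  - ", v, "\n", sep = "")
  invisible(x)
}
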