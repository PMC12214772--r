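test_that("demultiplexing assigns photons by arrival-phase window", {
  expect_equal(demultiplex(3, 14.3, 7.1), "imaging")
  expect_equal(demultiplex(10, 14.3, 7.1), "tracking")
  expect_equal(demultiplex(c(0, 7.14, 7.2, 14.2), 14.3, 7.1),
               c("imaging", "imaging", "tracking", "tracking"))
  expect_error(demultiplex(1, laser_period = 0), "positive")
  # Gaussian timing jitter of 1 ns misassigns well under 10% of photons
  set.seed(8)
  n <- 2e4
  period <- 1e9 / 7e7
  true_path <- rep(c("imaging", "tracking"), each = n / 2)
  center <- ifelse(true_path == "imaging", period / 4, period / 4 + 7.1)
  ph <- (center + rnorm(n, 0, 1)) %% period
  mis <- mean(demultiplex(ph) != true_path)
  expect_lt(mis, 0.10)
})

test_that("emission locations subtract the tracker and support raw mode", {
  cfg <- scan_config(A_tag = 25)
  s <- data.frame(t_s = 1e-3, x_galvo_um = 50, y_galvo_um = 60,
                  x_tracker_um = 10, y_tracker_um = 20, z_tracker_um = 0,
                  phi_rad = pi / 3, z_off_um = 0.5)
  loc <- emission_location(s, cfg)
  expect_equal(unlist(loc), c(x_um = 40, y_um = 40, z_um = 12))
  raw <- emission_location(s, cfg, raw = TRUE)
  expect_equal(unlist(raw), c(x_um = 50, y_um = 60, z_um = 12))
})

test_that("event location uses the nearest preceding sample and photon-time phase", {
  cfg <- scan_config(f_tag = 1e5, A_tag = 20)
  line_t <- 1 / (2 * cfg$f_tag)
  n <- 10
  s <- data.frame(t_s = (seq_len(n) - 0.5) * line_t,
                  x_galvo_um = seq_len(n), y_galvo_um = 2 * seq_len(n),
                  x_tracker_um = 1, y_tracker_um = 1, z_tracker_um = 0,
                  phi_rad = ((seq_len(n) - 0.5) * pi) %% (2 * pi),
                  z_off_um = 0)
  ev <- data.frame(t_s = c(0.6, 3.2) * line_t)
  out <- locate_events(ev, s, cfg)
  expect_equal(out$x_um, c(1 - 1, 4 - 1))
  expect_equal(out$z_um, cfg$A_tag * cos(2 * pi * cfg$f_tag * ev$t_s))
  expect_error(locate_events(data.frame(t_s = 100), s, cfg), "unaligned")
})

test_that("dwell adjustment follows |sin(phi)|/norm and excludes turnarounds", {
  cfg <- scan_config()
  expect_equal(dwell_adjust(1, pi / 2, cfg), 1 / 0.7846)
  expect_equal(dwell_adjust(1, pi / 6, cfg), 0.5 / 0.7846)
  expect_true(is.na(dwell_adjust(1, 0.1, cfg)))       # < 20 deg of turnaround
  expect_true(is.na(dwell_adjust(1, pi - 0.1, cfg)))
  expect_false(is.na(dwell_adjust(1, pi + 0.4, cfg)))
  # recomputed normalization: mean |sin phi| over the included band
  expect_equal(dwell_norm_const(20, "uniform_phi"),
               2 * cos(20 * pi / 180) / (pi - 2 * 20 * pi / 180))
  expect_equal(dwell_norm_const(), 0.7846)
})

test_that("volume assembly recovers a z-invariant rate with the derived scale", {
  # uniform-rate phantom: one huge 'blob' so the rate is flat over the field
  scan <- demo_scan()
  ph <- build_phantom(phantom_config(
    cell_radius = 1e4, n_segments = 1, red_rate = 5e5, green_base = 0,
    background_rate = 0, tracked_rate_mult = 1,
    bouts = data.frame(state = "other", start = 0, end = 1)))
  traj <- pong_trajectory(scan, 0.12)
  samples <- make_scan_samples(traj, NULL)
  set.seed(2)
  ev <- emit_photons(ph, samples, scan, powers = c(red = 1, green = 0))
  red <- locate_events(ev, samples, scan)
  geom <- make_geometry(c(-40, 40, -20, 20, -20, 20))
  vol <- assemble_volume(red, samples, scan, geom)
  # per-voxel line time share
  expect_equal(1 / (2 * 1.9e5 * 25), 105.3e-9, tolerance = 1e-3)
  # the |sin|/0.7846 convention recovers rate * 2/(pi * 0.7846) uniformly:
  # z-line-average is invariant in z (the purpose of the correction)
  # 4 overlapping giant blobs (1 medial + 2 lateral + tracked cell)
  expected <- 4 * 5e5 * 2 / (pi * scan$norm_const)
  zprof <- apply(vol$rate, 3, mean, na.rm = TRUE)
  inner <- zprof[4:17]   # away from the turnaround exclusion
  expect_lt(stats::sd(inner) / mean(inner), 0.05)
  expect_equal(mean(inner), expected, tolerance = 0.05)
  # count conservation: histogram total equals the summed adjustments of
  # retained in-domain events
  w <- dwell_adjust(rep(1, nrow(red)), red$phi_rad, scan)
  inside <- !is.na(w) & red$x_um >= -40 & red$x_um < 40 &
    red$y_um >= -20 & red$y_um < 20 & red$z_um >= -20 & red$z_um < 20
  expect_equal(sum(vol$counts), sum(w[inside]), tolerance = 1e-6)
  # voxel never scanned -> missing
  expect_true(all(is.na(vol$rate[vol$dwell == 0])))
})

test_that("tracker-corrected reconstruction is sharper than raw for a moving phantom", {
  scan <- demo_scan()
  ph <- build_phantom(phantom_config(
    bouts = data.frame(state = "forward", start = 0, end = 1.5),
    wave_amplitude = 0))
  traj <- pong_trajectory(scan, 1.4)
  truth <- data.frame(t_s = seq(0, 1.5, by = 1e-3))
  pos <- tracked_cell_path(ph, truth$t_s)
  truth$x_um <- pos[, 1]; truth$y_um <- pos[, 2]; truth$z_um <- pos[, 3]
  samples <- make_scan_samples(traj, truth)   # perfect tracker
  set.seed(6)
  ev <- emit_photons(ph, samples, scan, powers = c(red = 1, green = 0))
  red_c <- locate_events(ev, samples, scan)
  red_r <- locate_events(ev, samples, scan, raw = TRUE)
  geom <- make_geometry(c(-60, 60, -25, 25, -16, 16), spacing = c(2, 2, 4))
  vol_c <- assemble_volume(red_c, samples, scan, geom)
  vol_r <- assemble_volume(red_r, samples, scan, geom, raw = TRUE)
  contrast <- function(v) {
    r <- v$rate[!is.na(v$rate)]
    stats::quantile(r, 0.999) / (mean(r) + 1e-12)
  }
  expect_gt(contrast(vol_c), contrast(vol_r))
})

test_that("movie assembly defaults, conservation and constancy", {
  scan <- demo_scan()
  # 0.187 s characteristic time -> 94 ms default movie step
  cfg_pub <- scan_config(a_x = 200, r_xy = 1, dx = 0.8, tau_min = 3e-6,
                         f_max = 667)
  expect_equal(round(1000 * raster_characteristic_time(cfg_pub) / 2), 94)
  ph <- static_phantom()
  traj <- pong_trajectory(scan, 0.12)
  samples <- make_scan_samples(traj, NULL)
  set.seed(3)
  ev <- emit_photons(ph, samples, scan)
  ev <- locate_events(ev, samples, scan)
  geom <- make_geometry(c(-40, 40, -20, 20, -16, 16), spacing = c(2, 2, 4))
  mv <- assemble_movie(ev, samples, scan, geom, time_bin = 0.03)
  expect_equal(dim(mv$red$counts)[4], 4)
  mv0 <- assemble_movie(ev, samples, scan, geom, time_bin = 0.03,
                        smooth = FALSE)
  # the separable Gaussian kernel sums to 1: an interior impulse keeps its
  # total mass through the 4D smoother
  imp <- array(0, c(15, 15, 15, 11)); imp[8, 8, 8, 6] <- 7
  expect_equal(sum(pongscope:::gauss_smooth_nd(imp, c(1, 1, 1, 1))), 7,
               tolerance = 1e-12)
  # constant-rate phantom -> bins agree within noise at a bright voxel
  pk <- which(mv0$dwell[, , , 2] == max(mv0$dwell[, , , 2]), arr.ind = TRUE)[1, ]
  r2 <- mv$red$rate[pk[1], pk[2], pk[3], 2]
  r3 <- mv$red$rate[pk[1], pk[2], pk[3], 3]
  expect_equal(r2, r3, tolerance = 0.5)
})

test_that("template smoothing fills gaps robustly and evaluates continuously", {
  geom <- make_geometry(c(0, 30, 0, 20, 0, 10), spacing = c(2, 2, 2))
  d <- geom$dims
  # complete flat input passes through exactly
  flat <- structure(list(counts = array(5, d), dwell = array(1, d),
                         rate = array(5, d), origin = geom$origin,
                         spacing = geom$spacing, dims = d, n_z = d[3],
                         qc = list()), class = "rate_volume")
  tm <- smooth_template(flat)
  expect_equal(max(abs(tm$rate - 5)) / 5, 0, tolerance = 1e-6)
  # interior missing voxel between 2 and 4 -> filled within [2, 4]
  r <- array(rep(c(2, 4), length.out = prod(d)), d)
  dw <- array(1, d)
  r[8, 5, 3] <- NA; dw[8, 5, 3] <- 0
  vol <- structure(list(counts = r, dwell = dw, rate = r,
                        origin = geom$origin, spacing = geom$spacing,
                        dims = d, n_z = d[3], qc = list()),
                   class = "rate_volume")
  tm2 <- smooth_template(vol)
  expect_gte(tm2$rate[8, 5, 3], 2)
  expect_lte(tm2$rate[8, 5, 3], 4)
  # smooth Gaussian blob with 30% of voxels deleted: RMS error < 5% of peak
  set.seed(12)
  ctr <- lapply(1:3, function(ax)
    geom$origin[ax] + (seq_len(d[ax]) - 0.5) * geom$spacing[ax])
  pts <- as.matrix(expand.grid(ctr[[1]], ctr[[2]], ctr[[3]]))
  lam <- 100 * exp(-((pts[, 1] - 15)^2 + (pts[, 2] - 10)^2) / 60 -
                     (pts[, 3] - 5)^2 / 30)
  rate <- array(lam, d)
  dw <- array(1, d)
  kill <- sample(prod(d), round(0.3 * prod(d)))
  rate[kill] <- NA; dw[kill] <- 0
  vol3 <- structure(list(counts = rate, dwell = dw, rate = rate,
                         origin = geom$origin, spacing = geom$spacing,
                         dims = d, n_z = d[3], qc = list()),
                    class = "rate_volume")
  tm3 <- smooth_template(vol3)
  expect_lt(sqrt(mean((tm3$rate - array(lam, d))^2)), 0.05 * 100)
  # insufficient coverage errors out
  dw0 <- array(0, d); dw0[1:5] <- 1
  vol4 <- vol3; vol4$dwell <- dw0
  expect_error(smooth_template(vol4), "sampled")
  # continuous evaluation matches the grid at voxel centers
  v <- template_eval(tm3, pts[100:110, ])
  expect_equal(v, tm3$rate[100:110], tolerance = 1e-9)
})
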