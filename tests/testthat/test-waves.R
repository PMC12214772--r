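test_that("clipped baseline iterates one-sided and handles degenerate input", {
  expect_equal(baseline_clip(c(2, 2, 2, 2)), 2)
  # hand iteration: mean 3.25, sd clips the 10, converges to 1
  expect_equal(baseline_clip(c(1, 1, 1, 10)), 1)
  # non-increasing across iterations (one-sided clipping)
  set.seed(51)
  x <- c(rnorm(50, 1, 0.1), rnorm(10, 5, 1))
  b <- baseline_clip(x)
  expect_lte(b, mean(x))
  expect_equal(b, 1, tolerance = 0.2)
  expect_error(baseline_clip(c(1, 2)), "at least 3")
})

# a tiny synthetic rate movie built directly from arrays
toy_movie <- function(green, red, dwell = NULL, time_bin = 1) {
  d <- dim(green)
  if (is.null(dwell)) dwell <- array(1, d)
  rate_g <- green / dwell
  rate_r <- red / dwell
  structure(list(
    dwell = dwell, t_edges = 0:(d[4]) * time_bin,
    origin = c(0, 0, 0), spacing = c(2, 2, 2), dims = d[1:3],
    time_bin = time_bin,
    red = list(counts = red, rate = rate_r),
    green = list(counts = green, rate = rate_g)
  ), class = "rate_movie")
}

test_that("VOI ratios report green/red rates with baseline normalization", {
  d <- c(10, 8, 4, 20)
  red <- array(3, d)
  green <- 2 * red   # green = 2x red everywhere
  mv <- toy_movie(green, red)
  vois <- data.frame(x_um = 10, y_um = 8, z_um = 4, r_um = 5, name = "v1")
  tr <- voi_ratio(mv, vois, normalize = "none")
  expect_equal(tr$ratio, rep(2, 20))
  trn <- voi_ratio(mv, vois)
  expect_equal(trn$ratio_norm, rep(1, 20))   # flat trace: baseline = value
  # a transient above baseline survives normalization as > 1
  green2 <- green
  green2[, , , 10:12] <- green[, , , 10:12] * 3
  trn2 <- voi_ratio(toy_movie(green2, red), vois)
  expect_equal(mean(trn2$ratio_norm[1:5]), 1, tolerance = 0.01)
  expect_gt(trn2$ratio_norm[11], 2.5)
  # zero-dwell bin is missing
  dw <- array(1, d); dw[, , , 5] <- 0
  tr3 <- voi_ratio(toy_movie(green, red, dw), vois, normalize = "none")
  expect_true(is.na(tr3$ratio[5]))
})

test_that("time-space projection is median-normalized and shows wave ridges", {
  d <- c(24, 6, 3, 30)
  red <- array(2, d)
  green <- array(0, d)
  x <- (seq_len(d[1]) - 0.5) * 2
  tt <- seq_len(d[4])
  c_wave <- 1.5  # um per time bin
  for (b in tt)
    green[, , , b] <- 2 * (1.2 + cos(0.4 * (x - c_wave * b)))
  mv <- toy_movie(green, red)
  pr <- timespace_projection(mv, c(0, 48, 0, 12, 0, 6))
  expect_equal(stats::median(pr$map, na.rm = TRUE), 1)
  # ridge slope via the spatial-fundamental phase: d(phi)/d(bin) = 0.4*c
  ph_b <- vapply(seq_len(d[4]), function(b)
    Arg(sum(pr$map[, b] * exp(-1i * 0.4 * pr$x_um))), 0)
  dph <- diff(ph_b)
  dph <- (dph + pi) %% (2 * pi) - pi
  expect_equal(-mean(dph) / 0.4, c_wave, tolerance = 0.05)
  # uniform movie projects to 1 everywhere
  pr0 <- timespace_projection(toy_movie(red, red), c(0, 48, 0, 12, 0, 6))
  expect_true(all(abs(pr0$map - 1) < 1e-12))
})

test_that("stride averaging bins by phase into 15-degree bins", {
  expect_equal(2 * pi / 24, 15 * pi / 180)  # 24 bins = 15 degrees
  scan <- demo_scan()
  set.seed(52)
  # synthetic located events: uniform positions, times spread over strides
  n <- 60000
  ev <- data.frame(t_s = runif(n, 0, 6), x_um = runif(n, -40, 40),
                   y_um = runif(n, -20, 20), z_um = 0,
                   phi_rad = runif(n, 0.6, pi - 0.6))
  tt <- seq(0, 6, by = 1e-3)
  clock <- data.frame(t_s = tt, phi_rad = (2 * pi * tt / 1.5) %% (2 * pi),
                      phi_unwrapped = 2 * pi * tt / 1.5)
  strides <- data.frame(start = (0:3) * 1.5, end = (1:4) * 1.5, k = 0:3)
  samples <- data.frame(t_s = sort(runif(2e4, 0, 6)),
                        x_galvo_um = runif(2e4, -40, 40),
                        y_galvo_um = runif(2e4, -20, 20),
                        x_tracker_um = 0, y_tracker_um = 0, z_tracker_um = 0,
                        phi_rad = pi / 2, z_off_um = 0)
  geom <- make_geometry(c(-40, 40, -20, 20, -2, 2), spacing = c(8, 8, 4))
  cube <- stride_average(ev, samples, scan, clock, strides, geometry = geom)
  expect_equal(dim(cube$rate)[3], 24)
  expect_equal(cube$n_strides, 4)
  # phase-independent signal -> cube flat in phi within noise
  prof <- apply(cube$rate, 3, mean, na.rm = TRUE)
  expect_lt(stats::sd(prof) / mean(prof), 0.1)
})

test_that("wave PCA extracts quadrature sinusoids and the plane-wave fit", {
  set.seed(53)
  cube <- plane_wave_cube(k = c(0.11, 0))
  dec <- wave_pca(cube)
  expect_gte(dec$var_frac2, 0.99)
  nb <- length(dec$c1)
  f1 <- sum(dec$c1 * exp(-2i * pi * (seq_len(nb) - 1) / nb))
  f2 <- sum(dec$c2 * exp(-2i * pi * (seq_len(nb) - 1) / nb))
  off <- Arg(f1 * Conj(f2)) * 180 / pi
  expect_lt(abs(off - 90), 5)
  expect_gte(dec$c1[1], 0)
  # orthonormal components
  expect_equal(sum(dec$c1^2), 1, tolerance = 1e-9)
  expect_equal(sum(dec$c1 * dec$c2), 0, tolerance = 1e-9)
  # phase gradient slope = k within 5%
  fit <- wave_variance_explained(cube, dec)
  expect_gte(fit$variance_explained, 0.95)
  expect_equal(sqrt(sum(fit$k^2)), 0.11, tolerance = 0.05)
  # reversing the wave flips the phase gradient, |g| unchanged
  cube_r <- stride_cube(cube$rate[, , rev(seq_len(dim(cube$rate)[3]))],
                        cube$x_um, cube$y_um)
  dec_r <- wave_pca(cube_r)
  fit_r <- wave_variance_explained(cube_r, dec_r)
  expect_equal(sum(fit$k * fit_r$k) / (sqrt(sum(fit$k^2)) *
                                         sqrt(sum(fit_r$k^2))), -1,
               tolerance = 0.05)
  expect_equal(abs(dec_r$g), abs(dec$g), tolerance = 1e-6)
  # variance-explained never exceeds the two-component share
  expect_lte(fit$variance_explained, fit$variance_explained_pca + 1e-9)
})

test_that("phase-shuffled and zero-amplitude cubes do not mimic a wave", {
  set.seed(54)
  ve <- vapply(1:5, function(i) {
    cube <- plane_wave_cube(shuffle_phase = TRUE)
    fit <- wave_variance_explained(cube, wave_pca(cube))
    fit$variance_explained
  }, 0)
  expect_true(all(ve <= 0.1))
  # zero-amplitude cube -> 0 by convention
  cube0 <- stride_cube(array(rnorm(30 * 12 * 24, 0, 1e-14) + 3,
                             c(30, 12, 24)))
  dec0 <- tryCatch(wave_pca(cube0), error = function(e) NULL)
  if (!is.null(dec0)) {
    dec0$g[] <- 0
    fit0 <- wave_variance_explained(cube0, dec0)
    expect_equal(fit0$variance_explained, 0)
  }
  expect_true(TRUE)
})

test_that("ratiometry cancels shared intensity fields", {
  d <- c(12, 10, 3, 16)
  set.seed(55)
  base_r <- array(runif(prod(d[1:3]), 1, 3), d[1:3])
  mod_t <- 1 + 0.5 * sin(seq_len(d[4]))
  red <- green <- array(0, d)
  for (b in seq_len(d[4])) {
    red[, , , b] <- base_r * mod_t[b]
    green[, , , b] <- 2 * base_r * mod_t[b]
  }
  vois <- data.frame(x_um = 12, y_um = 10, z_um = 3, r_um = 8)
  tr <- voi_ratio(toy_movie(green, red), vois)
  # any positive shared spatial/temporal field leaves the ratio untouched
  expect_equal(tr$ratio_norm, rep(1, d[4]), tolerance = 1e-9)
})

test_that("bout statistics compare forward and backward with a rank-sum test", {
  set.seed(56)
  mk_trace <- function(means, sd = 0.05, nb = 10) {
    tt <- seq(0, nb - 0.01, by = 0.1)
    bout_id <- floor(tt) + 1
    data.frame(t_s = tt, ratio_norm = rnorm(length(tt), means[bout_id], sd))
  }
  bouts <- data.frame(state = rep(c("forward", "backward"), 5),
                      start = 0:9, end = 1:10)
  # null: identical distributions -> p mostly above 0.05
  p_null <- vapply(1:60, function(i) {
    tr <- mk_trace(rep(1, 10))
    bout_stats(tr, bouts)$p_backward_greater
  }, 0)
  expect_gte(mean(p_null >= 0.05), 0.9)
  # backward gain 1.5x -> strongly significant at 5 bouts per state
  means <- ifelse(bouts$state == "backward", 1.5, 1)
  p_alt <- bout_stats(mk_trace(means), bouts)$p_backward_greater
  expect_lt(p_alt, 0.01)
  # single bout in one state: medians reported, test skipped
  b2 <- data.frame(state = c("forward", "forward", "forward", "backward"),
                   start = 0:3, end = 1:4)
  bs2 <- bout_stats(mk_trace(c(1, 1, 1, 1.2), nb = 4), b2)
  expect_equal(bs2$flag, "too-few-bouts")
  expect_true(is.na(bs2$p_backward_greater))
  expect_length(bs2$medians, 2)
})
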