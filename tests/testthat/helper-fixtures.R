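# Shared fixtures, built in code at test time.

# small-field scan configuration used by the simulation tests
demo_scan <- function() {
  scan_config(a_x = 80, r_xy = 2, tau_min = 5.2e-6, dx = 1, f_max = 1200,
              A_tag = 20)
}

# stationary phantom (no bouts -> no motion, no wave)
static_phantom <- function(...) {
  build_phantom(phantom_config(
    bouts = data.frame(state = "other", start = 0, end = 1), ...))
}

# analytic template: the phantom's red rate field sampled on a voxel grid
analytic_template <- function(ph, extent = c(-40, 40, -24, 24, -16, 16),
                              spacing = c(2, 2, 2), t = 0) {
  geom <- make_geometry(extent, spacing)
  ctr <- lapply(1:3, function(ax)
    geom$origin[ax] + (seq_len(geom$dims[ax]) - 0.5) * geom$spacing[ax])
  pts <- as.matrix(expand.grid(ctr[[1]], ctr[[2]], ctr[[3]]))
  st <- pongscope:::blob_state_at(ph, t)
  lam <- pongscope:::rate_at_points(ph, pts, st)$red
  structure(list(rate = array(lam, geom$dims), origin = geom$origin,
                 spacing = geom$spacing, dims = geom$dims),
            class = "scan_template")
}

# draw n photons directly from the phantom's red blob mixture at time t
draw_blob_photons <- function(ph, n, t = 0) {
  st <- pongscope:::blob_state_at(ph, t)
  j <- sample(length(st$amp_red), n, replace = TRUE, prob = st$amp_red)
  cbind(st$centers[j, 1] + rnorm(n, 0, ph$sigma_lateral),
        st$centers[j, 2] + rnorm(n, 0, ph$sigma_lateral),
        st$centers[j, 3] + rnorm(n, 0, ph$sigma_axial))
}

# analytic plane-wave stride cube: rate = base + amp(x,y)*cos(k.x - phi)
plane_wave_cube <- function(nx = 30, ny = 12, nb = 24, k = c(0.11, 0),
                            base = 5, amp_mod = 0.3, shuffle_phase = FALSE) {
  x <- seq_len(nx) * 2
  y <- seq_len(ny) * 2
  phi <- (seq_len(nb) - 0.5) * 2 * pi / nb
  amp <- 1 + amp_mod * outer(sin(x / 15), cos(y / 10))
  spat <- if (shuffle_phase) matrix(runif(nx * ny, 0, 2 * pi), nx, ny)
    else outer(x * k[1], y * k[2], "+")
  arr <- array(0, c(nx, ny, nb))
  for (b in seq_len(nb)) arr[, , b] <- base + 2 * amp * cos(spat - phi[b])
  stride_cube(arr, x, y)
}

# circular RMS difference (offset removed) between two wrapped phases, rad
phase_rms <- function(a, b) {
  d <- (a - b + pi) %% (2 * pi) - pi
  off <- atan2(mean(sin(d)), mean(cos(d)))
  d2 <- (d - off + pi) %% (2 * pi) - pi
  sqrt(mean(d2^2))
}

# noisy tracked path + heading from the phantom's pose truth
phantom_track <- function(ph, t_end, dt = 0.005, noise_um = 1) {
  tt <- seq(0, t_end, by = dt)
  po <- pose_at(ph, tt)
  list(track = data.frame(t_s = tt,
                          x_um = po$translation[, 1] + rnorm(length(tt), 0, noise_um),
                          y_um = po$translation[, 2] + rnorm(length(tt), 0, noise_um)),
       heading = data.frame(t_s = tt, hx = po$heading[, 1],
                            hy = po$heading[, 2]))
}
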