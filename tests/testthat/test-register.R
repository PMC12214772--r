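test_that("rigid transform composes rotations and translation correctly", {
  tf <- rigid_transform(c(pi / 2, 0, 0), c(1, 2, 3))
  p <- rigid_apply(tf, rbind(c(1, 0, 0)))
  expect_equal(as.numeric(p), c(0 + 1, 1 + 2, 0 + 3), tolerance = 1e-12)
  # inverse round trip
  tf2 <- rigid_transform(c(0.3, 0.1, -0.2), c(5, -3, 2))
  pts <- matrix(rnorm(30), 10, 3)
  expect_equal(pongscope:::rigid_inverse_apply(tf2, rigid_apply(tf2, pts)),
               pts, tolerance = 1e-12)
})

test_that("rigid objective is order-invariant, additive, and peaked at truth", {
  set.seed(31)
  ph <- static_phantom()
  tmpl <- analytic_template(ph)
  pts <- draw_blob_photons(ph, 5000)
  w <- rep(1, nrow(pts))
  o1 <- pongscope:::rigid_objective(rep(0, 6), pts, w, tmpl)
  perm <- sample(nrow(pts))
  o2 <- pongscope:::rigid_objective(rep(0, 6), pts[perm, ], w, tmpl)
  expect_equal(o1, o2)
  # additivity under frame concatenation (sums add; here per-photon means
  # combine with photon-count weights)
  a <- pts[1:2000, ]; b <- pts[2001:5000, ]
  oa <- pongscope:::rigid_objective(rep(0, 6), a, w[1:2000], tmpl)
  ob <- pongscope:::rigid_objective(rep(0, 6), b, w[2001:5000], tmpl)
  expect_equal((2000 * oa + 3000 * ob) / 5000, o1, tolerance = 1e-12)
  # objective at the true transform beats identity for a rotated frame
  tf <- rigid_transform(c(0.3, 0, 0), c(4, -2, 0))
  fr <- pongscope:::rigid_inverse_apply(tf, pts)
  o_true <- pongscope:::rigid_objective(c(tf$angles, tf$translation), fr, w,
                                        tmpl)
  o_id <- pongscope:::rigid_objective(rep(0, 6), fr, w, tmpl)
  expect_gt(o_true, o_id)
})

test_that("rigid registration recovers identity and a 10 deg / (5,-3,2) um pose", {
  set.seed(32)
  ph <- static_phantom()
  tmpl <- analytic_template(ph)
  # self-registration
  tf0 <- rigid_register(draw_blob_photons(ph, 3e4), tmpl)
  ang0 <- (tf0$angles * 180 / pi + 180) %% 360 - 180
  expect_lt(max(abs(ang0)), 0.5)
  expect_lt(max(abs(tf0$translation)), 0.3)
  # known pose, >= 1e5 photons
  tf_true <- rigid_transform(c(10 * pi / 180, 0, 0), c(5, -3, 2))
  fr <- pongscope:::rigid_inverse_apply(tf_true, draw_blob_photons(ph, 1e5))
  tf <- rigid_register(fr, tmpl)
  d_ang <- (tf$angles - tf_true$angles) * 180 / pi
  d_ang <- (d_ang + 180) %% 360 - 180
  expect_lt(max(abs(d_ang)), 1)
  expect_lt(max(abs(tf$translation - tf_true$translation)), 0.5)
  # photon count below threshold -> unregistered flag
  tfu <- rigid_register(draw_blob_photons(ph, 50), tmpl)
  expect_false(attr(tfu, "registered"))
})

test_that("sequence registration reduces jitter and tracks a rotation ramp", {
  set.seed(33)
  ph <- static_phantom()
  tmpl <- analytic_template(ph)
  # static phantom: continuity shrinks frame-to-frame parameter scatter
  frames <- lapply(1:6, function(i) draw_blob_photons(ph, 1500))
  tfs_free <- register_sequence(frames, tmpl, continuity_weight = 0)
  tfs_cont <- register_sequence(frames, tmpl, continuity_weight = 0.05)
  scat <- function(tfs) {
    p <- t(vapply(tfs, function(tf) c(tf$angles, tf$translation), numeric(6)))
    mean(apply(p, 2, sd))
  }
  expect_lt(scat(tfs_cont), scat(tfs_free) + 1e-9)
  # linear in-plane rotation ramp 0 -> 20 deg over frames
  angs <- seq(0, 20, length.out = 5) * pi / 180
  frames2 <- lapply(angs, function(a)
    pongscope:::rigid_inverse_apply(rigid_transform(c(a, 0, 0), c(0, 0, 0)),
                                    draw_blob_photons(ph, 2e4)))
  tfs2 <- register_sequence(frames2, tmpl, continuity_weight = 0.005)
  rec <- vapply(tfs2, function(tf) (tf$angles[1] * 180 / pi + 180) %% 360 - 180,
                0)
  expect_lt(max(abs(rec - angs * 180 / pi)), 1)
})

test_that("nonrigid registration recovers a known bend and is null-stable", {
  set.seed(34)
  ph <- static_phantom()
  geom <- make_geometry(c(-40, 40, -20, 20, -10, 10), spacing = c(2, 2, 2))
  d <- geom$dims
  ctr <- lapply(1:3, function(ax)
    geom$origin[ax] + (seq_len(d[ax]) - 0.5) * geom$spacing[ax])
  pts <- as.matrix(expand.grid(ctr[[1]], ctr[[2]], ctr[[3]]))
  st <- pongscope:::blob_state_at(ph, 0)
  lam <- pongscope:::rate_at_points(ph, pts, st)$red
  tmpl <- structure(list(rate = array(lam, d), origin = geom$origin,
                         spacing = geom$spacing, dims = d),
                    class = "scan_template")
  as_vol <- function(r) structure(
    list(counts = array(r, d), dwell = array(1, d), rate = array(r, d),
         origin = geom$origin, spacing = geom$spacing, dims = d, n_z = d[3],
         qc = list()), class = "rate_volume")
  # null recovery: undeformed frame -> mean displacement < 0.5 um
  v0 <- as_vol(lam * exp(rnorm(length(lam), 0, 0.05)))
  f0 <- nonrigid_register(v0, tmpl)
  u0 <- ffd_displacement(f0, pts[lam > 0.05 * max(lam), ])
  expect_lt(mean(sqrt(rowSums(u0^2))), 0.5)
  # known 10 um in-plane bend
  truth <- ffd_field(c(-40, -20, -10), c(40, 20, 20), c(3, 3, 2))
  truth$grid[, , , 2] <- 10 * outer(sin(seq(-1, 1, length.out = 3) * pi / 2),
                                    rep(1, 3))
  u <- ffd_displacement(truth, pts)
  v1 <- as_vol(template_eval(tmpl, pts + u) *
                 exp(rnorm(length(lam), 0, 0.05)))
  f1 <- nonrigid_register(v1, tmpl)
  tissue <- lam > 0.05 * max(lam)
  resid <- sqrt(rowSums((ffd_displacement(f1, pts[tissue, ]) -
                           u[tissue, ])^2))
  expect_lt(mean(resid), 2)
  # dual application: warping scan-path coordinates agrees with resampling
  # the image (same field, two uses) within interpolation error
  warped_path <- template_eval(tmpl, pts + ffd_displacement(f1, pts))
  expect_lt(sqrt(mean((warped_path - as.numeric(v1$rate))^2, na.rm = TRUE)) /
              max(lam), 0.07)
})

test_that("intensity correction recovers constant and gradient multipliers", {
  set.seed(35)
  ph <- static_phantom()
  tmpl <- analytic_template(ph)
  m <- 2e4
  path <- cbind(runif(m, -38, 38), runif(m, -22, 22), runif(m, -14, 14))
  lam <- template_eval(tmpl, path)
  dt <- 7e-5   # per-sample dwell: ~ 10^5 photons over the path
  cases <- list(constant = function(p) rep(0.8, nrow(p)),
                gradient = function(p) 1 - 0.4 * (p[, 1] + 40) / 80)
  for (nm in names(cases)) {
    a <- cases[[nm]](path)
    cnt <- rpois(m, a * lam * dt)
    fld <- intensity_correct(path[rep.int(seq_len(m), cnt), , drop = FALSE],
                             path, dt, tmpl)
    est <- scalar_field_eval(fld, path)
    sig <- lam > 0.1 * max(lam)
    expect_lt(sqrt(mean((est[sig] - a[sig])^2)), 0.05)
  }
  # undimmed frame -> alpha within 5% of 1 where sampled
  cnt <- rpois(m, lam * dt)
  fld1 <- intensity_correct(path[rep.int(seq_len(m), cnt), , drop = FALSE],
                            path, dt, tmpl)
  est1 <- scalar_field_eval(fld1, path)
  sig <- lam > 0.1 * max(lam)
  expect_lt(max(abs(est1[sig] - 1)), 0.15)
  expect_lt(sqrt(mean((est1[sig] - 1)^2)), 0.05)
  # degenerate: no photons -> alpha = 1 with flag
  fld0 <- intensity_correct(path[0, , drop = FALSE], path, dt, tmpl)
  expect_equal(attr(fld0, "flag"), "degenerate")
  expect_equal(scalar_field_eval(fld0, rbind(c(0, 0, 0))), 1)
})

test_that("corrections come from red only and apply identically to both channels", {
  set.seed(36)
  ph <- static_phantom()
  tmpl <- analytic_template(ph)
  mk_ev <- function(n) {
    p <- draw_blob_photons(ph, n)
    data.frame(t_s = seq_len(n) * 1e-6, x_um = p[, 1], y_um = p[, 2],
               z_um = p[, 3])
  }
  red <- mk_ev(5000)
  green <- mk_ev(3000)
  tf <- rigid_transform(c(0.1, 0, 0), c(1, -1, 0))
  alpha <- scalar_field(c(-40, -24, -16), c(40, 24, 16), c(3, 3, 3),
                        array(0.8, c(3, 3, 3)))
  out <- apply_corrections(red, green, tf, NULL, alpha, NULL)
  # both channels mapped through the same transform
  expect_equal(as.matrix(out$red[, c("x_um", "y_um", "z_um")]),
               unname(rigid_apply(tf, as.matrix(red[, c("x_um", "y_um",
                                                        "z_um")]))),
               tolerance = 1e-12, ignore_attr = TRUE)
  # out-of-domain events are dropped and tallied when a template is given
  out_t <- apply_corrections(red, green, tf, NULL, alpha, tmpl)
  expect_equal(nrow(out_t$red) + out_t$qc$dropped_red, nrow(red))
  expect_equal(unique(round(out$green$weight, 10)), round(1 / 0.8, 10))
  # identity corrections leave events unchanged
  out0 <- apply_corrections(red, green, NULL, NULL, NULL, NULL)
  expect_equal(out0$red$x_um, red$x_um)
  # green stream never influences the corrections: permuting green changes
  # nothing about what is applied
  out_perm <- apply_corrections(red, green[sample(nrow(green)), ], tf, NULL,
                                alpha, tmpl)
  expect_equal(sort(out_perm$green$x_um), sort(out$green$x_um))
})
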