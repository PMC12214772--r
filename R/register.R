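#' Rigid transform (three rotations + translation)
#'
#' Rotation is applied as in-plane rotation about z first, then small tilts
#' about x and y; then the translation is added. The transform maps frame
#' (scan-path) coordinates into template coordinates.
#'
#' @param angles length-3 (rad): in-plane angle, tilt about x, tilt about y.
#' @param translation length-3 (um).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0)) {
  structure(list(angles = as.numeric(angles),
                 translation = as.numeric(translation)),
            class = "rigid_transform")
}

rigid_matrix <- function(tf) {
  a <- tf$angles
  Rz <- rbind(c(cos(a[1]), -sin(a[1]), 0), c(sin(a[1]), cos(a[1]), 0),
              c(0, 0, 1))
  Rx <- rbind(c(1, 0, 0), c(0, cos(a[2]), -sin(a[2])),
              c(0, sin(a[2]), cos(a[2])))
  Ry <- rbind(c(cos(a[3]), 0, sin(a[3])), c(0, 1, 0),
              c(-sin(a[3]), 0, cos(a[3])))
  Ry %*% Rx %*% Rz
}

#' Apply a rigid transform to points
#'
#' @param tf a [rigid_transform()].
#' @param pts n x 3 matrix.
#' @return n x 3 matrix.
#' @export
rigid_apply <- function(tf, pts) {
  pts <- rbind(pts)
  sweep(pts %*% t(rigid_matrix(tf)), 2, -tf$translation)
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @return a function-equivalent inverse as a list with `matrix` and
#'   `translation` applied as `R^-1 (x - t)`.
#' @keywords internal
rigid_inverse_apply <- function(tf, pts) {
  pts <- rbind(pts)
  sweep(pts, 2, tf$translation) %*% rigid_matrix(tf)
}

# photon-correlation objective: mean template rate at transformed photon
# locations (Eq.-style sum over photons, normalized by count so values are
# comparable across frames)
rigid_objective <- function(par, pts, w, template) {
  tf <- rigid_transform(par[1:3], par[4:6])
  lam <- template_eval(template, rigid_apply(tf, pts))
  sum(w * lam) / sum(w)
}

#' Rigid registration of one frame of photons to a template
#'
#' Finds the rigid transform maximizing the summed template rate over the
#' frame's photon locations. Optimization is staged: a coarse grid over the
#' in-plane angle (the sample can be oriented at any angle in the plane)
#' with 2D translation refinement, then a derivative-free 6-parameter
#' refinement (three rotations, 3D translation) warm-started from the
#' stage-1 optimum.
#'
#' @param pts n x 3 matrix of located photon coordinates (um), or a located
#'   event table with `x_um`, `y_um`, `z_um`.
#' @param template a [smooth_template()] result.
#' @param weights optional per-photon weights.
#' @param angle_step coarse grid step (degrees).
#' @param init optional initial transform (skips the angle grid).
#' @param min_photons frames with fewer photons are flagged unregistered.
#' @param max_photons photons are subsampled beyond this count.
#' @return a `rigid_transform` with attributes `objective` and `registered`.
#' @export
rigid_register <- function(pts, template, weights = NULL, angle_step = 10,
                           init = NULL, min_photons = 200L,
                           max_photons = 60000L) {
  if (is.data.frame(pts)) pts <- as.matrix(pts[, c("x_um", "y_um", "z_um")])
  n <- nrow(pts)
  if (is.null(weights)) weights <- rep(1, n)
  if (n < min_photons) {
    tf <- rigid_transform()
    attr(tf, "registered") <- FALSE
    attr(tf, "objective") <- NA_real_
    return(tf)
  }
  if (n > max_photons) {
    keep <- seq(1L, n, length.out = max_photons)
    pts <- pts[keep, , drop = FALSE]
    weights <- weights[keep]
  }
  n <- nrow(pts)
  sub <- seq(1L, n, length.out = min(n, 15000L))  # coarse stage subsample
  if (is.null(init)) {
    angles <- seq(0, 2 * pi - 1e-9, by = angle_step * pi / 180)
    vals <- vapply(angles, function(a)
      rigid_objective(c(a, 0, 0, 0, 0, 0), pts[sub, , drop = FALSE],
                      weights[sub], template), 0)
    best <- angles[order(vals, decreasing = TRUE)[1:3]]
    cands <- lapply(best, function(a) {
      stats::optim(c(a, 0, 0), function(p)
        -rigid_objective(c(p[1], 0, 0, p[2], p[3], 0),
                         pts[sub, , drop = FALSE], weights[sub], template),
        method = "Nelder-Mead",
        control = list(maxit = 200, reltol = 1e-8))
    })
    s1 <- cands[[which.min(vapply(cands, `[[`, 0, "value"))]]
    p0 <- c(s1$par[1], 0, 0, s1$par[2], s1$par[3], 0)
  } else {
    p0 <- c(init$angles, init$translation)
  }
  s2 <- stats::optim(p0, function(p) -rigid_objective(p, pts, weights,
                                                      template),
                     method = "Nelder-Mead",
                     control = list(maxit = 600, reltol = 1e-9,
                                    parscale = c(0.05, 0.05, 0.05, 1, 1, 1)))
  tf <- rigid_transform(s2$par[1:3], s2$par[4:6])
  attr(tf, "objective") <- -s2$value
  attr(tf, "registered") <- TRUE
  tf
}

#' Register a sequence of frames with temporal continuity
#'
#' Each frame is first registered independently (or from supplied initial
#' transforms), then refined by Gauss-Seidel sweeps of the per-frame
#' objective plus a quadratic penalty on successive parameter differences.
#' With zero continuity weight the refinement reduces to independent fits.
#'
#' @param frames list of photon matrices (or located event tables).
#' @param template a [smooth_template()].
#' @param continuity_weight penalty weight (objective units per squared
#'   parameter difference; angles in rad, translations in um).
#' @param init optional list of initial `rigid_transform`s.
#' @param sweeps Gauss-Seidel sweeps.
#' @param ... passed to [rigid_register()].
#' @return list of `rigid_transform`s.
#' @export
register_sequence <- function(frames, template, continuity_weight = 0.01,
                              init = NULL, sweeps = 2L, ...) {
  nf <- length(frames)
  tfs <- vector("list", nf)
  for (i in seq_len(nf)) {
    tfs[[i]] <- rigid_register(frames[[i]], template,
                               init = if (!is.null(init)) init[[i]] else
                                 if (i > 1) tfs[[i - 1]] else NULL, ...)
  }
  if (continuity_weight <= 0 || nf < 2) return(tfs)
  getp <- function(tf) c(tf$angles, tf$translation)
  pars <- t(vapply(tfs, getp, numeric(6)))
  prep <- lapply(frames, function(f) {
    if (is.data.frame(f)) as.matrix(f[, c("x_um", "y_um", "z_um")]) else f
  })
  scale <- c(rep(10, 3), rep(1, 3))  # a radian is worth ~10 um of mismatch
  for (s in seq_len(sweeps)) {
    for (i in seq_len(nf)) {
      nbrs <- pars[c(if (i > 1) i - 1, if (i < nf) i + 1), , drop = FALSE]
      obj <- function(p) {
        pen <- sum(vapply(seq_len(nrow(nbrs)), function(j)
          sum(((p - nbrs[j, ]) * scale)^2), 0))
        -rigid_objective(p, prep[[i]], rep(1, nrow(prep[[i]])), template) +
          continuity_weight * pen
      }
      o <- stats::optim(pars[i, ], obj, method = "Nelder-Mead",
                        control = list(maxit = 200, reltol = 1e-8))
      pars[i, ] <- o$par
    }
  }
  lapply(seq_len(nf), function(i) {
    tf <- rigid_transform(pars[i, 1:3], pars[i, 4:6])
    attr(tf, "registered") <- TRUE
    tf
  })
}

#' Non-rigid (B-spline FFD) registration of a frame volume to a template
#'
#' Estimates a free-form deformation `T` such that the template evaluated
#' at `x + T(x)` matches the (rigid-registered) frame volume, by maximizing
#' the missing-data-aware normalized correlation over sampled voxels with a
#' bending-energy penalty on the control grid. The returned field applies
#' to scan-path coordinates of both channels.
#'
#' @param frame_vol a [assemble_volume()] result (rigid-registered frame).
#' @param template a [smooth_template()].
#' @param grid_spacing control-point spacing (um).
#' @param bend_weight bending-energy weight.
#' @param in_plane logical; restrict displacements to x-y.
#' @param maxit optimizer iteration cap.
#' @return an `ffd_field` with attribute `converged`.
#' @export
nonrigid_register <- function(frame_vol, template, grid_spacing = 20,
                              bend_weight = 1e-4, in_plane = TRUE,
                              maxit = 150L) {
  stopifnot(inherits(frame_vol, "rate_volume"))
  mask <- frame_vol$dwell > 0 & is.finite(frame_vol$rate)
  idx <- which(mask, arr.ind = TRUE)
  pts <- cbind(frame_vol$origin[1] + (idx[, 1] - 0.5) * frame_vol$spacing[1],
               frame_vol$origin[2] + (idx[, 2] - 0.5) * frame_vol$spacing[2],
               frame_vol$origin[3] + (idx[, 3] - 0.5) * frame_vol$spacing[3])
  b <- frame_vol$rate[mask]
  # keep voxels carrying signal in either image
  lam0 <- template_eval(template, pts)
  keep <- b > 0 | lam0 > 0.05 * max(lam0)
  pts <- pts[keep, , drop = FALSE]
  b <- b[keep]
  ext <- apply(pts, 2, range)
  dims <- pmax(2L, as.integer(ceiling((ext[2, ] - ext[1, ]) / grid_spacing)) + 1L)
  if (in_plane) dims[3] <- max(1L, min(dims[3], 2L))
  spacing <- (ext[2, ] - ext[1, ] + 1e-6) / pmax(dims - 1, 1)
  spacing[spacing <= 0] <- grid_spacing
  field <- ffd_field(ext[1, ], spacing, dims)
  ncp <- prod(dims)
  B <- bspline_basis(field$origin, field$spacing, field$dims, pts)
  bhat <- b - mean(b)
  sb <- sqrt(sum(bhat^2))
  ncomp <- if (in_plane) 2L else 3L
  h <- 0.25   # um step for template gradient
  objgrad <- function(theta) {
    G <- matrix(theta, ncp, ncomp)
    disp <- B %*% G
    q <- pts
    q[, 1:ncomp] <- q[, 1:ncomp] + disp
    a <- template_eval(template, q)
    ahat <- a - mean(a)
    sa <- sqrt(sum(ahat^2))
    if (sa < 1e-12 || sb < 1e-12) return(list(value = 1e6, grad = 0 * theta))
    ncc <- sum(ahat * bhat) / (sa * sb)
    dna <- (bhat / (sa * sb)) - (ncc / sa^2) * ahat
    grad <- matrix(0, ncp, ncomp)
    for (ax in seq_len(ncomp)) {
      qp <- q; qp[, ax] <- qp[, ax] + h
      qm <- q; qm[, ax] <- qm[, ax] - h
      gax <- (template_eval(template, qp) - template_eval(template, qm)) /
        (2 * h)
      grad[, ax] <- crossprod(B, dna * gax)
    }
    gridc <- array(0, c(dims, 3))
    gridc[, , , 1:ncomp] <- array(G, c(dims, ncomp))
    be <- bending_energy(gridc, with_grad = TRUE)
    val <- -ncc + bend_weight * be$value
    gr <- -grad + bend_weight *
      matrix(be$grad[, , , 1:ncomp, drop = FALSE], ncp, ncomp)
    list(value = val, grad = as.numeric(gr))
  }
  theta0 <- numeric(ncp * ncomp)
  o <- stats::optim(theta0, fn = function(p) objgrad(p)$value,
                    gr = function(p) objgrad(p)$grad,
                    method = "L-BFGS-B",
                    control = list(maxit = maxit, factr = 1e9))
  G <- matrix(o$par, ncp, ncomp)
  field$grid[, , , 1:ncomp] <- array(G, c(dims, ncomp))
  attr(field, "converged") <- o$convergence %in% c(0L, 1L)
  if (o$convergence > 1L) {
    field$grid[] <- 0
    warning("nonrigid_register did not converge; returning identity field",
            call. = FALSE)
  }
  field
}

#' Poisson-MLE intensity correction field
#'
#' Finds a smooth multiplier `alpha(x)` to the template rate maximizing the
#' inhomogeneous-Poisson log-likelihood of the observed photons,
#' `sum(log alpha(x_i)) - integral(alpha(x(t)) * lambda(x(t)) dt)`,
#' with `alpha` parameterized by cubic B-spline control values on a
#' `grid_spacing` lattice (positivity enforced by a lower bound of 0.05 on
#' the control values).
#'
#' @param photon_pts n x 3 matrix of (registered) photon locations of the
#'   frame.
#' @param path_pts m x 3 matrix of (registered) scan-path sample locations.
#' @param path_dt dwell time per path sample (s), scalar or length m.
#' @param template a [smooth_template()].
#' @param grid_spacing control spacing (um).
#' @return a `bspline_scalar_field` (alpha), with attribute `flag`
#'   (`"ok"` or `"degenerate"`).
#' @export
intensity_correct <- function(photon_pts, path_pts, path_dt, template,
                              grid_spacing = 20) {
  photon_pts <- rbind(photon_pts)
  path_pts <- rbind(path_pts)
  if (nrow(photon_pts) == 0L) {
    fld <- scalar_field(c(0, 0, 0), rep(grid_spacing, 3), c(1, 1, 1))
    attr(fld, "flag") <- "degenerate"
    return(fld)
  }
  lam <- template_eval(template, path_pts)
  dt <- rep_len(path_dt, nrow(path_pts))
  ext <- apply(rbind(photon_pts, path_pts), 2, range)
  dims <- pmax(2L, as.integer(ceiling((ext[2, ] - ext[1, ]) /
                                        grid_spacing)) + 1L)
  spacing <- (ext[2, ] - ext[1, ] + 1e-6) / pmax(dims - 1, 1)
  fld <- scalar_field(ext[1, ], spacing, dims)
  Bp <- bspline_basis(fld$origin, fld$spacing, fld$dims, photon_pts)
  Bs <- bspline_basis(fld$origin, fld$spacing, fld$dims, path_pts)
  lamdt <- lam * dt
  neg_ll <- function(theta) {
    a_ph <- pmax(Bp %*% theta, 1e-8)
    -(sum(log(a_ph)) - sum((Bs %*% theta) * lamdt))
  }
  neg_grad <- function(theta) {
    a_ph <- pmax(Bp %*% theta, 1e-8)
    -(as.numeric(crossprod(Bp, 1 / a_ph)) - as.numeric(crossprod(Bs, lamdt)))
  }
  o <- stats::optim(rep(1, prod(dims)), neg_ll, neg_grad, method = "L-BFGS-B",
                    lower = 0.05, upper = 100,
                    control = list(maxit = 300, factr = 1e8))
  fld$values <- array(o$par, dims)
  attr(fld, "flag") <- "ok"
  fld
}

#' Apply the red-channel corrections to both channels
#'
#' Maps located events through the rigid transform and the deformation
#' field, and divides per-event weights by the intensity multiplier at the
#' corrected location. Corrections are computed from the red channel only
#' and applied identically to both channels; events landing outside the
#' template domain are dropped and tallied.
#'
#' @param events_red,events_green located event tables (`x_um`, `y_um`,
#'   `z_um`, optional `weight`).
#' @param rigid a [rigid_transform()] (or `NULL` for identity).
#' @param ffd an `ffd_field` (or `NULL`).
#' @param alpha a `bspline_scalar_field` (or `NULL`).
#' @param template template defining the valid domain (optional; no
#'   dropping if absent).
#' @return list with corrected `red`, `green` tables and a `qc` tally.
#' @export
apply_corrections <- function(events_red, events_green, rigid = NULL,
                              ffd = NULL, alpha = NULL, template = NULL) {
  fix <- function(ev) {
    if (nrow(ev) == 0L) return(list(ev = ev, dropped = 0L))
    pts <- as.matrix(ev[, c("x_um", "y_um", "z_um")])
    if (!is.null(rigid)) pts <- rigid_apply(rigid, pts)
    if (!is.null(ffd)) pts <- pts + ffd_displacement(ffd, pts)
    if (!("weight" %in% names(ev))) ev$weight <- 1
    if (!is.null(alpha))
      ev$weight <- ev$weight / pmax(scalar_field_eval(alpha, pts), 0.05)
    ev$x_um <- pts[, 1]; ev$y_um <- pts[, 2]; ev$z_um <- pts[, 3]
    dropped <- 0L
    if (!is.null(template)) {
      lo <- template$origin
      hi <- template$origin + template$dims * template$spacing
      ok <- pts[, 1] >= lo[1] & pts[, 1] < hi[1] &
        pts[, 2] >= lo[2] & pts[, 2] < hi[2] &
        pts[, 3] >= lo[3] & pts[, 3] < hi[3]
      dropped <- sum(!ok)
      ev <- ev[ok, , drop = FALSE]
    }
    list(ev = ev, dropped = dropped)
  }
  r <- fix(events_red)
  g <- fix(events_green)
  list(red = r$ev, green = g$ev,
       qc = list(dropped_red = r$dropped, dropped_green = g$dropped))
}
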