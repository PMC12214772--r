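# Uniform cubic B-spline machinery shared by the free-form deformation
# (FFD) field, the intensity multiplier field, and their estimation.
# Control points sit on a regular grid; evaluation clamps indices at the
# grid edge (constant extrapolation outside the control lattice).

bspline3_weights <- function(f) {
  cbind((1 - f)^3 / 6,
        (3 * f^3 - 6 * f^2 + 4) / 6,
        (-3 * f^3 + 3 * f^2 + 3 * f + 1) / 6,
        f^3 / 6)
}

#' Cubic B-spline basis matrix on a 3D control grid
#'
#' Returns the dense matrix `B` (`nrow(pts)` x `prod(dims)`) such that a
#' field with control values `theta` evaluates to `B %*% theta` at `pts`.
#' Each point receives tensor-product weights from its 4x4x4 control-point
#' neighborhood; indices are clamped at the lattice edge.
#'
#' @param origin control point (1,1,1) coordinates.
#' @param spacing control-point spacing per axis.
#' @param dims control-grid dimensions (length 3).
#' @param pts n x 3 matrix of evaluation points.
#' @return dense numeric matrix.
#' @keywords internal
bspline_basis <- function(origin, spacing, dims, pts) {
  n <- nrow(pts)
  ncp <- prod(dims)
  B <- matrix(0, n, ncp)
  gidx <- list(); gw <- list()
  for (ax in 1:3) {
    u <- (pts[, ax] - origin[ax]) / spacing[ax]
    i0 <- floor(u)
    f <- u - i0
    w <- bspline3_weights(f)
    idx <- vapply(-1:2, function(d) pmin(pmax(i0 + d, 0), dims[ax] - 1),
                  numeric(n))
    if (n == 1L) idx <- matrix(idx, nrow = 1L)
    gidx[[ax]] <- idx
    gw[[ax]] <- w
  }
  for (a in 1:4) for (b in 1:4) for (c in 1:4) {
    w <- gw[[1]][, a] * gw[[2]][, b] * gw[[3]][, c]
    col <- 1 + gidx[[1]][, a] + dims[1] * (gidx[[2]][, b] +
                                             dims[2] * gidx[[3]][, c])
    # accumulate (several of the 64 combos can hit the same clamped column)
    B[cbind(seq_len(n), col)] <- B[cbind(seq_len(n), col)] + w
  }
  B
}

#' Create an (identity) B-spline free-form deformation field
#'
#' @param origin,spacing,dims control-lattice geometry (see
#'   [bspline_basis()]).
#' @return object of class `ffd_field` with a `dims x 3` displacement grid
#'   initialized to zero.
#' @export
ffd_field <- function(origin, spacing, dims) {
  stopifnot(length(dims) == 3, all(dims >= 1), all(spacing > 0))
  structure(list(origin = origin, spacing = spacing, dims = as.integer(dims),
                 grid = array(0, c(dims, 3))),
            class = "ffd_field")
}

#' Evaluate an FFD displacement field
#'
#' @param field an [ffd_field()].
#' @param pts n x 3 matrix of points.
#' @return n x 3 matrix of displacements (um).
#' @export
ffd_displacement <- function(field, pts) {
  stopifnot(inherits(field, "ffd_field"))
  pts <- rbind(pts)
  B <- bspline_basis(field$origin, field$spacing, field$dims, pts)
  ncp <- prod(field$dims)
  g <- matrix(field$grid, ncp, 3)
  B %*% g
}

#' Maximum displacement magnitude of an FFD field on its control grid
#' @param field an [ffd_field()].
#' @return um.
#' @export
ffd_max_displacement <- function(field) {
  g <- matrix(field$grid, prod(field$dims), 3)
  sqrt(max(rowSums(g^2)))
}

# Bending-energy proxy: sum of squared second differences of the control
# values along each lattice axis (per component). Returns the value and,
# optionally, the gradient with respect to the control values.
bending_energy <- function(grid, with_grad = FALSE) {
  d <- dim(grid)
  dims <- d[1:3]
  ncomp <- if (length(d) == 4) d[4] else 1
  g <- array(grid, c(dims, ncomp))
  val <- 0
  grad <- if (with_grad) array(0, dim(g)) else NULL
  for (ax in 1:3) {
    if (dims[ax] < 3) next
    n <- dims[ax]
    perm <- c(ax, setdiff(1:3, ax), 4)
    gp <- aperm(g, perm)
    m <- matrix(gp, nrow = n)
    dd <- m[1:(n - 2), , drop = FALSE] - 2 * m[2:(n - 1), , drop = FALSE] +
      m[3:n, , drop = FALSE]
    val <- val + sum(dd^2)
    if (with_grad) {
      gm <- matrix(0, n, ncol(m))
      gm[1:(n - 2), ] <- gm[1:(n - 2), ] + 2 * dd
      gm[2:(n - 1), ] <- gm[2:(n - 1), ] - 4 * dd
      gm[3:n, ] <- gm[3:n, ] + 2 * dd
      ga <- array(gm, dim(gp))
      grad <- grad + aperm(ga, order(perm))
    }
  }
  if (with_grad) list(value = val, grad = array(grad, dim(grid)))
  else val
}

#' Create a scalar cubic B-spline field (e.g., an intensity multiplier)
#'
#' @param origin,spacing,dims control-lattice geometry.
#' @param values control values (default 1 everywhere).
#' @return object of class `bspline_scalar_field`.
#' @export
scalar_field <- function(origin, spacing, dims, values = NULL) {
  stopifnot(length(dims) == 3, all(dims >= 1))
  if (is.null(values)) values <- array(1, dims)
  structure(list(origin = origin, spacing = spacing, dims = as.integer(dims),
                 values = array(values, dims)),
            class = "bspline_scalar_field")
}

#' Evaluate a scalar B-spline field
#'
#' @param field a [scalar_field()].
#' @param pts n x 3 matrix.
#' @return numeric vector.
#' @export
scalar_field_eval <- function(field, pts) {
  pts <- rbind(pts)
  B <- bspline_basis(field$origin, field$spacing, field$dims, pts)
  as.numeric(B %*% as.numeric(field$values))
}
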