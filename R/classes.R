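#' Section image container
#'
#' One digitized autoradiograph section. Pixels are stored as a matrix with
#' the first index along x and the second along y; physical coordinates of
#' pixel `(i, j)` (1-based) are `((i-1)*dx, (j-1)*dy)` micrometres. Values are
#' either 8-bit gray levels (0--255) or calibrated activities in nCi/g.
#'
#' @param pixels numeric matrix of gray levels or activities.
#' @param spacing in-plane pixel spacing `(dx, dy)` in micrometres.
#' @param index 0-based position of the section in the anterior-to-posterior
#'   order of its subject.
#' @param mask optional logical matrix of the same shape marking tissue.
#' @return An object of class `section_image`.
#' @export
section_image <- function(pixels, spacing = c(10, 10), index = 0L,
                          mask = NULL) {
  stopifnot(is.matrix(pixels), length(spacing) == 2, all(spacing > 0))
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == dim(pixels)))
  }
  structure(list(pixels = pixels, spacing = as.numeric(spacing),
                 index = as.integer(index), mask = mask),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("<section_image> %d x %d px, spacing (%g, %g) um, index %d%s\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              x$index, if (is.null(x$mask)) "" else ", masked"))
  invisible(x)
}

#' 3D volume container
#'
#' Ordered 3D grid of activities with anisotropic physical spacing. The world
#' coordinate of voxel `(i, j, k)` (1-based) is
#' `origin + ((i-1)*dx, (j-1)*dy, (k-1)*dz)`.
#'
#' @param voxels 3D numeric array.
#' @param spacing voxel spacing `(dx, dy, dz)` in micrometres.
#' @param mask optional logical array of the same shape.
#' @param origin physical coordinates of voxel `(1, 1, 1)` in micrometres.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(voxels, spacing = c(10, 10, 20), mask = NULL,
                     origin = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3,
            length(spacing) == 3, all(spacing > 0), length(origin) == 3)
  if (is.null(mask)) mask <- array(TRUE, dim(voxels))
  stopifnot(is.logical(mask), all(dim(mask) == dim(voxels)))
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 mask = mask, origin = as.numeric(origin)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<volume3d> %d x %d x %d voxels, spacing (%g, %g, %g) um, %d in mask\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    sum(x$mask)))
  invisible(x)
}

#' @rdname volume3d
#' @param x a `volume3d`.
#' @export
volume_center <- function(x) {
  x$origin + (dim(x$voxels) - 1) * x$spacing / 2
}

section_center <- function(s) {
  (dim(s$pixels) - 1) * s$spacing / 2
}

# ---------------------------------------------------------------------------
# In-plane rigid transforms: T(x) = R_theta (x - c) + c + t, physical um.

#' In-plane rigid transform
#'
#' 3-degree-of-freedom rigid map of 2D physical coordinates,
#' `T(x) = R(theta) (x - center) + center + (tx, ty)`, used both to perturb
#' phantom sections and to realign sections during reconstruction. Resampling
#' is by backward mapping: the output image at `x` takes the input value at
#' `T(x)`.
#'
#' @param tx,ty translation in micrometres.
#' @param theta rotation in degrees (counter-clockwise).
#' @param center rotation center in physical coordinates (micrometres).
#' @return An object of class `rigid2d`.
#' @export
rigid2d <- function(tx = 0, ty = 0, theta = 0, center = c(0, 0)) {
  structure(list(tx = tx, ty = ty, theta = theta,
                 center = as.numeric(center)), class = "rigid2d")
}

#' @export
print.rigid2d <- function(x, ...) {
  cat(sprintf("<rigid2d> t = (%.3f, %.3f) um, theta = %.4f deg\n",
              x$tx, x$ty, x$theta))
  invisible(x)
}

#' Apply, compose and invert transforms
#'
#' `tf_apply` maps physical points (rows of `pts`) through a transform;
#' `tf_compose(a, b)` returns the map `x -> a(b(x))` (both transforms must
#' share a rotation center); `tf_inverse` returns the exact inverse.
#'
#' @param tf,a,b transform objects (`rigid2d` or `affine3d`).
#' @param pts numeric matrix of points, one per row.
#' @return A matrix of mapped points, or a transform object.
#' @export
tf_apply <- function(tf, pts) UseMethod("tf_apply")

#' @rdname tf_apply
#' @export
tf_compose <- function(a, b) UseMethod("tf_compose")

#' @rdname tf_apply
#' @export
tf_inverse <- function(tf) UseMethod("tf_inverse")

rot2 <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' @export
tf_apply.rigid2d <- function(tf, pts) {
  pts <- rbind(pts)
  R <- rot2(tf$theta)
  sweep(sweep(pts, 2, tf$center) %*% t(R), 2,
        tf$center + c(tf$tx, tf$ty), `+`)
}

#' @export
tf_compose.rigid2d <- function(a, b) {
  stopifnot(inherits(b, "rigid2d"),
            max(abs(a$center - b$center)) < 1e-9)
  tb <- rot2(a$theta) %*% c(b$tx, b$ty)
  rigid2d(tx = tb[1] + a$tx, ty = tb[2] + a$ty, theta = a$theta + b$theta,
          center = a$center)
}

#' @export
tf_inverse.rigid2d <- function(tf) {
  t2 <- -rot2(-tf$theta) %*% c(tf$tx, tf$ty)
  rigid2d(tx = t2[1], ty = t2[2], theta = -tf$theta, center = tf$center)
}

# ---------------------------------------------------------------------------
# 12-DOF affine transforms of 3D physical coordinates.

#' 12-parameter affine transform in 3D
#'
#' `T(x) = M (x - center) + center + translation` on physical coordinates
#' (micrometres). Used for inter-subject normalization; removes rotation,
#' translation, scaling and shearing differences between reconstructed
#' volumes.
#'
#' @param matrix invertible 3x3 linear part.
#' @param translation length-3 translation in micrometres.
#' @param center fixed point of the linear part, physical coordinates.
#' @return An object of class `affine3d`.
#' @export
affine3d <- function(matrix = diag(3), translation = c(0, 0, 0),
                     center = c(0, 0, 0)) {
  matrix <- base::matrix(as.numeric(matrix), 3, 3)
  if (abs(det(matrix)) <= 1e-12) stop("affine matrix is singular")
  structure(list(matrix = matrix, translation = as.numeric(translation),
                 center = as.numeric(center)), class = "affine3d")
}

#' @export
print.affine3d <- function(x, ...) {
  cat("<affine3d> matrix:\n")
  print(round(x$matrix, 5))
  cat(sprintf("translation (%.2f, %.2f, %.2f) um\n",
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' @export
tf_apply.affine3d <- function(tf, pts) {
  pts <- rbind(pts)
  sweep(sweep(pts, 2, tf$center) %*% t(tf$matrix), 2,
        tf$center + tf$translation, `+`)
}

#' @export
tf_compose.affine3d <- function(a, b) {
  stopifnot(inherits(b, "affine3d"),
            max(abs(a$center - b$center)) < 1e-9)
  affine3d(matrix = a$matrix %*% b$matrix,
           translation = as.numeric(a$matrix %*% b$translation) +
             a$translation,
           center = a$center)
}

#' @export
tf_inverse.affine3d <- function(tf) {
  Mi <- solve(tf$matrix)
  affine3d(matrix = Mi, translation = as.numeric(-Mi %*% tf$translation),
           center = tf$center)
}

# ---------------------------------------------------------------------------
# Cubic B-spline free-form deformation on a regular control grid.

#' Cubic B-spline free-form deformation
#'
#' Smooth (C2) displacement field `D(x)` parameterized by displacement
#' vectors on a regular control-point grid; the total normalization map is
#' `x -> A(x) + D(x)` with `A` the affine stage. Zero coefficients give the
#' identity displacement. The control grid must cover the image domain plus
#' the one-control-point support margin cubic splines require;
#' [bspline_grid()] constructs such a grid.
#'
#' @param origin physical position of the first control point (micrometres).
#' @param spacing control-point spacing per axis (micrometres).
#' @param shape integer triple of control points per axis.
#' @param coef 4D array `shape x 3` of displacement coefficients
#'   (micrometres), or `NULL` for all-zero.
#' @return An object of class `bspline3d`.
#' @export
bspline3d <- function(origin, spacing, shape, coef = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(origin) == 3, length(spacing) == 3, length(shape) == 3,
            all(spacing > 0), all(shape >= 4))
  if (is.null(coef)) coef <- array(0, c(shape, 3))
  stopifnot(all(dim(coef) == c(shape, 3)))
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 shape = shape, coef = coef), class = "bspline3d")
}

#' @export
print.bspline3d <- function(x, ...) {
  cat(sprintf(
    "<bspline3d> %d x %d x %d control points, spacing (%g, %g, %g) um, max |d| = %.3f um\n",
    x$shape[1], x$shape[2], x$shape[3], x$spacing[1], x$spacing[2],
    x$spacing[3], max(abs(x$coef))))
  invisible(x)
}

#' @rdname bspline3d
#' @param reference a `volume3d` whose domain the grid must cover.
#' @param grid_spacing requested control-point spacing per axis (micrometres);
#'   snapped so that an integer grid covers the domain.
#' @export
bspline_grid <- function(reference, grid_spacing) {
  stopifnot(inherits(reference, "volume3d"), length(grid_spacing) == 3)
  extent <- (dim(reference$voxels) - 1) * reference$spacing
  if (any(grid_spacing < 2 * reference$spacing)) {
    stop("invalid-grid: control spacing below 2 voxels on some axis")
  }
  n_int <- pmax(1L, as.integer(ceiling(extent / grid_spacing)))
  spacing <- extent / n_int
  # one extra control point each side for full cubic support
  shape <- n_int + 3L
  if (any(shape < 4L)) stop("invalid-grid: fewer than 4 control points")
  origin <- reference$origin - spacing
  bspline3d(origin = origin, spacing = spacing, shape = shape)
}

# Cubic B-spline basis matrix along one axis: n_points x n_ctrl, 4 nonzero
# weights per row. Coordinates in physical um.
bspline_basis_1d <- function(coords, origin, spacing, n_ctrl) {
  s <- (coords - origin) / spacing
  i0 <- floor(s)
  t <- s - i0
  w <- cbind((1 - t)^3, 3 * t^3 - 6 * t^2 + 4,
             -3 * t^3 + 3 * t^2 + 3 * t + 1, t^3) / 6
  B <- matrix(0, length(coords), n_ctrl)
  for (m in 0:3) {
    idx <- i0 - 1 + m + 1  # 1-based control index
    ok <- idx >= 1 & idx <= n_ctrl
    B[cbind(which(ok), idx[ok])] <- B[cbind(which(ok), idx[ok])] + w[ok, m + 1]
  }
  B
}

# Tensor-mode products: field F[i,j,k] = sum_{a,b,c} Bx[i,a] By[j,b] Bz[k,c] C[a,b,c]
tensor3_apply <- function(C, Bx, By, Bz) {
  d <- dim(C)
  m1 <- Bx %*% matrix(C, d[1], d[2] * d[3])              # nx x (b*c)
  a1 <- array(m1, c(nrow(Bx), d[2], d[3]))
  a1p <- aperm(a1, c(2, 1, 3))
  m2 <- By %*% matrix(a1p, d[2], nrow(Bx) * d[3])        # ny x (nx*c)
  a2 <- array(m2, c(nrow(By), nrow(Bx), d[3]))
  a2p <- aperm(a2, c(3, 2, 1))
  m3 <- Bz %*% matrix(a2p, d[3], nrow(Bx) * nrow(By))    # nz x (nx*ny)
  a3 <- array(m3, c(nrow(Bz), nrow(Bx), nrow(By)))
  aperm(a3, c(2, 3, 1))
}

# Dense displacement field of a bspline3d over a reference grid:
# returns n_voxels x 3 matrix in um (column-major voxel order).
bspline_displacement <- function(tf, reference) {
  d <- dim(reference$voxels)
  Bx <- bspline_basis_1d(reference$origin[1] + (0:(d[1] - 1)) *
                           reference$spacing[1],
                         tf$origin[1], tf$spacing[1], tf$shape[1])
  By <- bspline_basis_1d(reference$origin[2] + (0:(d[2] - 1)) *
                           reference$spacing[2],
                         tf$origin[2], tf$spacing[2], tf$shape[2])
  Bz <- bspline_basis_1d(reference$origin[3] + (0:(d[3] - 1)) *
                           reference$spacing[3],
                         tf$origin[3], tf$spacing[3], tf$shape[3])
  out <- matrix(0, prod(d), 3)
  for (ax in 1:3) {
    out[, ax] <- as.numeric(tensor3_apply(tf$coef[, , , ax], Bx, By, Bz))
  }
  out
}
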