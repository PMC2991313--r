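# Inter-subject spatial normalization: each reconstructed volume is warped
# onto a smoothed reference template by a 12-DOF affine stage followed by a
# cubic B-spline free-form deformation, both multi-resolution and driven by
# masked normalized cross-correlation.

#' Mask-aware Gaussian smoothing
#'
#' Separable Gaussian smoothing in physical units: per axis
#' `sigma = fwhm / (2 sqrt(2 ln 2)) ~ fwhm / 2.3548`, converted to voxels by
#' the axis spacing (anisotropic voxels give anisotropic kernels).
#' Normalized convolution restricted to the mask: both `v * mask` and
#' `mask` are smoothed and divided, so background zeros never bleed into
#' tissue. `fwhm = 0` on every axis returns the input unchanged.
#'
#' @param volume a `volume3d`.
#' @param fwhm full width at half maximum per axis, micrometres (length 3,
#'   or length 1 recycled).
#' @return Smoothed `volume3d`, same mask.
#' @export
smooth_gaussian <- function(volume, fwhm) {
  stopifnot(inherits(volume, "volume3d"), all(fwhm >= 0))
  fwhm <- rep(fwhm, length.out = 3)
  if (all(fwhm == 0)) return(volume)
  sigma_vox <- fwhm / (2 * sqrt(2 * log(2))) / volume$spacing
  num <- volume$voxels * volume$mask
  den <- volume$mask * 1
  for (ax in 1:3) {
    k <- gauss_kernel(sigma_vox[ax])
    if (length(k) == 1) next
    num <- conv1d_axis(num, k, ax)
    den <- conv1d_axis(den, k, ax)
  }
  out <- array(0, dim(volume$voxels))
  inm <- volume$mask & den > 1e-12
  out[inm] <- num[inm] / den[inm]
  volume3d(out, spacing = volume$spacing, mask = volume$mask,
           origin = volume$origin)
}

#' Prepare a reference template
#'
#' A designated reconstructed subject serves as the template; it is smoothed
#' once, before any registration, with FWHM equal to `fwhm_factor` times the
#' voxel size on each axis.
#'
#' @param template a `volume3d`.
#' @param fwhm_factor multiple of the voxel size (default 3).
#' @return Smoothed template `volume3d`.
#' @export
prepare_template <- function(template, fwhm_factor = 3) {
  stopifnot(fwhm_factor > 0)
  smooth_gaussian(template, fwhm = fwhm_factor * template$spacing)
}

# Masked NCC between a fixed volume and the moving volume under an affine
# (+ optional B-spline) map. Metric region = fixed mask intersected with
# the moving field of view (fixed-mask convention: continuous in the
# transform parameters, no mask-quantization jumps in the cost surface).
volume_ncc <- function(fixed, moving, affine, bspline = NULL) {
  disp <- if (is.null(bspline)) matrix(0, 0, 3) else
    bspline_displacement(bspline, fixed)
  cpp_ncc_affine3d(fixed$voxels, fixed$mask, dim(fixed$voxels),
                   fixed$spacing, fixed$origin, moving$voxels,
                   dim(moving$voxels), moving$spacing, moving$origin,
                   as.numeric(affine$matrix), affine$translation,
                   affine$center, disp)
}

# Plain (not mask-aware) Gaussian smoothing of the voxel data, used on the
# metric inputs of the registration stages: it suppresses both noise and
# the interpolation-induced ripple of the cost surface that sharp edges
# cause (a bilinearly resampled image is slightly smoother than its source,
# which otherwise biases the optimum toward integer-offset resampling).
smooth_metric <- function(volume, fwhm) {
  sigma_vox <- fwhm / (2 * sqrt(2 * log(2))) / volume$spacing
  vox <- volume$voxels
  for (ax in 1:3) {
    k <- gauss_kernel(sigma_vox[ax])
    if (length(k) > 1) vox <- conv1d_axis(vox, k, ax)
  }
  volume3d(vox, spacing = volume$spacing, mask = volume$mask,
           origin = volume$origin)
}

com_point <- function(volume) {
  d <- dim(volume$voxels)
  w <- volume$voxels * volume$mask
  tot <- sum(w)
  if (tot <= 0) return(volume_center(volume))
  gx <- volume$origin[1] + (0:(d[1] - 1)) * volume$spacing[1]
  gy <- volume$origin[2] + (0:(d[2] - 1)) * volume$spacing[2]
  gz <- volume$origin[3] + (0:(d[3] - 1)) * volume$spacing[3]
  c(sum(apply(w, 1, sum) * gx), sum(apply(w, 2, sum) * gy),
    sum(apply(w, 3, sum) * gz)) / tot
}

#' Affine (12-DOF) registration of two volumes
#'
#' Coarse-to-fine (default x4, x2, x1 block-mean pyramid) maximization of
#' masked NCC over the 12 affine parameters, initialized from
#' center-of-mass alignment, Nelder-Mead simplex per level (deterministic).
#' Parameters are internally scaled (linear part unitless, translation in
#' fixed-voxel units) so the simplex explores all degrees of freedom
#' comparably.
#'
#' @param fixed,moving `volume3d`s with overlapping fields of view.
#' @param levels integer downsampling factors, coarse to fine.
#' @param maxit simplex iteration caps per level (recycled).
#' @param metric_fwhm_factor Gaussian smoothing of the metric inputs, as a
#'   multiple of the voxel size (0 = none); regularizes the cost surface
#'   against noise and interpolation ripple without touching the output.
#' @param moving_resampled if `TRUE` (default), the fixed image receives a
#'   small additional blur matching the interpolation blur a once-resampled
#'   moving volume carries (reconstructed stacks are resampled products),
#'   symmetrizing the metric.
#' @return An `affine3d` with attribute `ncc` (final score) and
#'   `ncc_by_level`.
#' @export
register_affine_3d <- function(fixed, moving, levels = c(4, 2, 1),
                               maxit = c(4000, 2500, 1200),
                               metric_fwhm_factor = 3,
                               moving_resampled = TRUE) {
  stopifnot(inherits(fixed, "volume3d"), inherits(moving, "volume3d"))
  maxit <- rep(maxit, length.out = length(levels))
  ctr <- volume_center(fixed)
  t0 <- com_point(moving) - com_point(fixed)
  if (metric_fwhm_factor > 0) {
    sig <- metric_fwhm_factor / (2 * sqrt(2 * log(2)))
    # the moving image is interpolated twice (once at generation or
    # reconstruction, once by the metric itself), each pass adding ~1/6
    # voxel^2 of trilinear blur; matching the total on the fixed side
    # symmetrizes the metric, which otherwise biases the recovered scale
    # by ~1%
    sig_f <- if (moving_resampled) sqrt(sig^2 + 1 / 3) else sig
    fixed <- smooth_metric(fixed,
                           2 * sqrt(2 * log(2)) * sig_f * fixed$spacing)
    moving <- smooth_metric(moving, metric_fwhm_factor * moving$spacing)
  }
  sc_t <- max(fixed$spacing)
  par2tf <- function(p) {
    affine3d(matrix = diag(3) + matrix(p[1:9], 3, 3),
             translation = t0 + p[10:12] * sc_t, center = ctr)
  }
  p <- rep(0, 12)
  ncc_by_level <- numeric(0)
  for (li in seq_along(levels)) {
    f <- downsample_volume(fixed, levels[li])
    m <- downsample_volume(moving, levels[li])
    cost <- function(p) {
      s <- volume_ncc(f, m, par2tf(p))
      if (is.na(s)) 2 else -s
    }
    opt <- optim(p, cost, method = "Nelder-Mead",
                 control = list(maxit = maxit[li], reltol = 1e-12,
                                parscale = c(rep(0.05, 9), rep(1, 3))))
    if (li == 1 && opt$value >= 1.5) {
      stop("optimizer stall at coarsest level: no valid overlap found")
    }
    if (li == length(levels)) {
      # fresh-simplex restart at the finest level: 12-dim Nelder-Mead
      # routinely stalls short of its optimum once
      opt2 <- optim(opt$par, cost, method = "Nelder-Mead",
                    control = list(maxit = maxit[li], reltol = 1e-12,
                                   parscale = c(rep(0.05, 9), rep(1, 3))))
      if (opt2$value < opt$value) opt <- opt2
    }
    if (opt$value <= cost(p)) p <- opt$par
    ncc_by_level <- c(ncc_by_level, -opt$value)
  }
  out <- par2tf(p)
  attr(out, "ncc") <- volume_ncc(fixed, moving, out)
  attr(out, "ncc_by_level") <- ncc_by_level
  out
}

#' B-spline (free-form deformation) registration
#'
#' Optimizes the control-point displacements of a cubic B-spline field to
#' maximize masked NCC between the fixed volume and the moving volume under
#' the composition `x -> A(x) + D(x)` (affine stage `A` from
#' [register_affine_3d()], held fixed). Multi-resolution over control-grid
#' spacing: the default schedule halves the spacing once, from 1/4 to 1/8
#' of each axis extent; each grid level runs L-BFGS-B with the analytic NCC
#' gradient (image-gradient chain rule projected onto the spline basis).
#' Grid coarseness is the only regularization.
#'
#' @param fixed,moving `volume3d`s.
#' @param init an `affine3d` (identity if `NULL`).
#' @param grid_spacing control-point spacing of the finest level in
#'   micrometres (length 3), or `NULL` for 1/8 of each axis extent.
#' @param grid_levels number of grid levels (coarsest spacing =
#'   `grid_spacing * 2^(grid_levels - 1)`).
#' @param maxit L-BFGS-B iteration cap per level.
#' @param metric_fwhm_factor Gaussian smoothing of the metric inputs as a
#'   multiple of the voxel size (0 = none); see [register_affine_3d()].
#' @return A `bspline3d` with attributes `ncc` and `ncc_affine`.
#' @export
register_bspline_3d <- function(fixed, moving, init = NULL,
                                grid_spacing = NULL, grid_levels = 2,
                                maxit = 60, metric_fwhm_factor = 2) {
  stopifnot(inherits(fixed, "volume3d"), inherits(moving, "volume3d"))
  if (is.null(init)) init <- affine3d(center = volume_center(fixed))
  fixed_raw <- fixed
  moving_raw <- moving
  if (metric_fwhm_factor > 0) {
    fixed <- smooth_metric(fixed, metric_fwhm_factor * fixed$spacing)
    moving <- smooth_metric(moving, metric_fwhm_factor * moving$spacing)
  }
  extent <- (dim(fixed$voxels) - 1) * fixed$spacing
  if (is.null(grid_spacing)) {
    # 1/8 of the extent per axis, floored at the 2-voxel legality limit
    # (thin stacks would otherwise get sub-voxel control spacing)
    grid_spacing <- pmax(extent / 8, 2 * fixed$spacing)
  }
  if (any(grid_spacing < 2 * fixed$spacing)) {
    stop("invalid-grid: control spacing below 2 voxels on some axis")
  }
  if (any(extent / grid_spacing < 1)) {
    stop("invalid-grid: fewer than 4 control points of data support")
  }
  tf <- NULL
  for (lev in grid_levels:1) {
    gs <- grid_spacing * 2^(lev - 1)
    grid <- bspline_grid(fixed, gs)
    if (!is.null(tf)) {
      # initialize finer grid from the coarse field evaluated at its
      # control points (approximation; refined by the optimizer)
      pts <- as.matrix(expand.grid(
        grid$origin[1] + (0:(grid$shape[1] - 1)) * grid$spacing[1],
        grid$origin[2] + (0:(grid$shape[2] - 1)) * grid$spacing[2],
        grid$origin[3] + (0:(grid$shape[3] - 1)) * grid$spacing[3]))
      dsp <- bspline_eval_points(tf, pts)
      grid$coef <- array(dsp, c(grid$shape, 3))
    }
    grid <- optimize_bspline(fixed, moving, init, grid, maxit = maxit)
    tf <- grid
  }
  attr(tf, "ncc_affine") <- volume_ncc(fixed_raw, moving_raw, init)
  attr(tf, "ncc") <- volume_ncc(fixed_raw, moving_raw, init, tf)
  tf
}

# Displacement of a bspline3d at arbitrary physical points (n x 3),
# vectorized over the 4 x 4 x 4 support stencil.
bspline_eval_points <- function(tf, pts) {
  n <- nrow(pts)
  sh <- tf$shape
  s1 <- (pts[, 1] - tf$origin[1]) / tf$spacing[1]
  s2 <- (pts[, 2] - tf$origin[2]) / tf$spacing[2]
  s3 <- (pts[, 3] - tf$origin[3]) / tf$spacing[3]
  i0 <- floor(s1); j0 <- floor(s2); k0 <- floor(s3)
  bw <- function(t) cbind((1 - t)^3, 3 * t^3 - 6 * t^2 + 4,
                          -3 * t^3 + 3 * t^2 + 3 * t + 1, t^3) / 6
  wu <- bw(s1 - i0); wv <- bw(s2 - j0); ww <- bw(s3 - k0)
  out <- matrix(0, n, 3)
  cf <- matrix(tf$coef, prod(sh), 3)
  for (a in 0:3) {
    ia <- i0 - 1 + a
    oka <- ia >= 0 & ia <= sh[1] - 1
    for (b in 0:3) {
      jb <- j0 - 1 + b
      okb <- oka & jb >= 0 & jb <= sh[2] - 1
      for (cc in 0:3) {
        kc <- k0 - 1 + cc
        ok <- okb & kc >= 0 & kc <= sh[3] - 1
        if (!any(ok)) next
        lin <- ia[ok] + sh[1] * jb[ok] + sh[1] * sh[2] * kc[ok] + 1
        wgt <- wu[ok, a + 1] * wv[ok, b + 1] * ww[ok, cc + 1]
        out[ok, 1] <- out[ok, 1] + wgt * cf[lin, 1]
        out[ok, 2] <- out[ok, 2] + wgt * cf[lin, 2]
        out[ok, 3] <- out[ok, 3] + wgt * cf[lin, 3]
      }
    }
  }
  out
}

# L-BFGS-B on control-point displacements, analytic NCC gradient (exact
# gradient of the trilinear interpolant, chain rule through the spline
# basis).
optimize_bspline <- function(fixed, moving, affine, grid, maxit = 60) {
  d <- dim(fixed$voxels)
  gx <- fixed$origin[1] + (0:(d[1] - 1)) * fixed$spacing[1]
  gy <- fixed$origin[2] + (0:(d[2] - 1)) * fixed$spacing[2]
  gz <- fixed$origin[3] + (0:(d[3] - 1)) * fixed$spacing[3]
  Bx <- bspline_basis_1d(gx, grid$origin[1], grid$spacing[1], grid$shape[1])
  By <- bspline_basis_1d(gy, grid$origin[2], grid$spacing[2], grid$shape[2])
  Bz <- bspline_basis_1d(gz, grid$origin[3], grid$spacing[3], grid$shape[3])
  fx <- fixed$voxels
  fmask <- fixed$mask
  shape <- grid$shape
  nco <- prod(shape)
  eval_all <- function(theta) {
    co <- array(theta, c(shape, 3))
    disp <- matrix(0, prod(d), 3)
    for (ax in 1:3) {
      disp[, ax] <- as.numeric(tensor3_apply(co[, , , ax], Bx, By, Bz))
    }
    r <- cpp_sample_grad3d(moving$voxels, dim(moving$voxels),
                           moving$spacing, moving$origin,
                           as.numeric(affine$matrix), affine$translation,
                           affine$center, d, fixed$spacing, fixed$origin,
                           disp)
    m <- fmask   # fixed metric region; out-of-field reads as background 0
    nm <- sum(m)
    if (nm < 32) return(list(value = 2, grad = rep(0, 3 * nco)))
    a <- fx[m] - mean(fx[m])
    bvals <- r$value[m]
    b <- bvals - mean(bvals)
    Saa <- sum(a^2); Sbb <- sum(b^2); Sab <- sum(a * b)
    if (Saa == 0 || Sbb == 0) return(list(value = 2, grad = rep(0, 3 * nco)))
    den <- sqrt(Saa * Sbb)
    val <- Sab / den
    dj <- array(0, d)
    dj[m] <- (a - (Sab / Sbb) * b) / den
    grad <- numeric(3 * nco)
    gv <- list(r$gx, r$gy, r$gz)
    for (ax in 1:3) {
      q <- dj * gv[[ax]]
      grad[(ax - 1) * nco + seq_len(nco)] <-
        as.numeric(tensor3_apply(q, t(Bx), t(By), t(Bz)))
    }
    list(value = -val, grad = -grad)
  }
  cache <- new.env()
  fn <- function(theta) {
    r <- eval_all(theta)
    assign("g", r$grad, envir = cache)
    r$value
  }
  gr <- function(theta) get("g", envir = cache)
  opt <- optim(as.numeric(grid$coef), fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 1e4))
  grid$coef <- array(opt$par, c(shape, 3))
  grid
}

#' Warp a volume into a reference space
#'
#' Resamples `volume` onto the grid of `reference` under the normalization
#' map `x -> A(x) + D(x)` (backward mapping): linear interpolation for
#' intensities, nearest-neighbour for the mask, 0 outside the field of view.
#'
#' @param volume a `volume3d`.
#' @param affine an `affine3d` (identity if `NULL`).
#' @param bspline a `bspline3d` or `NULL`.
#' @param reference `volume3d` defining the output grid.
#' @return Warped `volume3d` on the reference grid.
#' @export
warp_volume <- function(volume, affine = NULL, bspline = NULL,
                        reference = volume) {
  if (is.null(affine)) affine <- affine3d(center = volume_center(reference))
  resample_volume(volume, affine = affine, bspline = bspline,
                  reference = reference)
}

#' Normalize one subject to a template
#'
#' Convenience wrapper: affine then B-spline registration to a prepared
#' (smoothed) template, returning the warped volume and both transforms.
#'
#' @param volume reconstructed subject `volume3d`.
#' @param template smoothed template `volume3d` (see [prepare_template()]).
#' @param grid_spacing,grid_levels,maxit_bspline passed to
#'   [register_bspline_3d()].
#' @return List `warped`, `affine`, `bspline`.
#' @export
normalize_to_template <- function(volume, template, grid_spacing = NULL,
                                  grid_levels = 2, maxit_bspline = 60) {
  aff <- register_affine_3d(template, volume)
  bsp <- register_bspline_3d(template, volume, init = aff,
                             grid_spacing = grid_spacing,
                             grid_levels = grid_levels,
                             maxit = maxit_bspline)
  list(warped = warp_volume(volume, aff, bsp, reference = template),
       affine = aff, bspline = bsp)
}
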