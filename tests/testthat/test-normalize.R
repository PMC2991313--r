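# Spatial normalization: smoothing identities, affine/B-spline transform
# algebra, registration recovery and warping semantics.

test_that("fwhm-sigma relation and smoothing identities hold", {
  expect_equal(30 / (2 * sqrt(2 * log(2))), 12.739827, tolerance = 1e-6)
  v <- make_phantom_volume(small_spec(seed = 1, noise_sd = 3))
  expect_identical(smooth_gaussian(v, 0)$voxels, v$voxels)
})

test_that("mask-aware smoothing preserves interior mass and ignores
           background", {
  d <- c(32, 32, 24)
  vox <- array(0, d)
  mask <- array(FALSE, d)
  mask[4:29, 4:29, 3:22] <- TRUE
  vox[15:17, 15:17, 11:13] <- 100   # blob fully interior to the mask
  v <- volume3d(vox, spacing = c(10, 10, 20), mask = mask)
  sm <- smooth_gaussian(v, fwhm = c(30, 30, 60))
  expect_lt(abs(sum(sm$voxels[mask]) / sum(vox) - 1), 1e-3)
  expect_true(all(sm$voxels[!mask] == 0))
  # background zeros must not drag the in-mask plateau down
  vox2 <- array(0, d)
  vox2[mask] <- 80
  sm2 <- smooth_gaussian(volume3d(vox2, spacing = c(10, 10, 20),
                                  mask = mask), fwhm = c(30, 30, 60))
  expect_lt(max(abs(sm2$voxels[mask] - 80)), 1e-9)
})

test_that("affine3d composes, inverts and rejects singular matrices", {
  set.seed(4)
  for (i in 1:20) {
    ctr <- runif(3, 0, 500)
    m1 <- diag(3) + matrix(rnorm(9, 0, 0.1), 3, 3)
    a1 <- affine3d(m1, runif(3, -50, 50), ctr)
    a2 <- affine3d(diag(3) + matrix(rnorm(9, 0, 0.1), 3, 3),
                   runif(3, -50, 50), ctr)
    id <- tf_compose(a1, tf_inverse(a1))
    expect_lt(max(abs(id$matrix - diag(3))), 1e-9)
    expect_lt(max(abs(id$translation)), 1e-9)
    pts <- matrix(runif(15, 0, 500), 5, 3)
    expect_equal(tf_apply(tf_compose(a1, a2), pts),
                 tf_apply(a1, tf_apply(a2, pts)), tolerance = 1e-9)
  }
  expect_error(affine3d(matrix(0, 3, 3)), "singular")
})

test_that("zero B-spline coefficients compose with an affine to the exact
           affine map", {
  v <- make_phantom_volume(small_spec(seed = 2))
  grid <- bspline_grid(v, (dim(v$voxels) - 1) * v$spacing / 3)
  expect_true(all(grid$coef == 0))
  a <- affine3d(diag(3) * 1.03, c(12, -5, 8), volume_center(v))
  w1 <- warp_volume(v, a, NULL, reference = v)
  w2 <- warp_volume(v, a, grid, reference = v)
  expect_equal(w1$voxels, w2$voxels, tolerance = 1e-12)
})

test_that("identity and integer-shift warps are exact", {
  v <- make_phantom_volume(small_spec(seed = 6, noise_sd = 2))
  w <- warp_volume(v, NULL, NULL, reference = v)
  expect_equal(w$voxels, v$voxels, tolerance = 1e-12)
  shift <- affine3d(translation = c(10, 0, 0), center = volume_center(v))
  ws <- warp_volume(v, shift, NULL, reference = v)
  expect_equal(ws$voxels[1:31, , ], v$voxels[2:32, , ], tolerance = 1e-12)
})

test_that("affine registration recovers itself and a known transform", {
  sp <- phantom_spec(grid_shape = c(64, 64, 40), noise_sd = 0,
                     z_profile = "closed", seed = 9)
  v <- make_phantom_volume(sp)
  self <- register_affine_3d(v, v, moving_resampled = FALSE)
  expect_lt(max(abs(self$matrix - diag(3))), 1e-3)
  expect_lt(max(abs(self$translation)), 5)   # 0.5 voxel in-plane
  ctr <- volume_center(v)
  th <- 5 * pi / 180
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  truth <- affine3d(1.06 * rot, c(25, -15, 15), ctr)
  mv <- warp_volume(v, truth, reference = padded_reference(v, 6L))
  rec <- register_affine_3d(v, mv)
  err <- affine_errors(rec, tf_inverse(truth))
  expect_lt(err$scale_pct, 1)
  expect_lt(err$rot_deg, 0.5)
  expect_lt(err$trans_um, 10)   # 0.5 voxel of the coarsest axis
})

test_that("B-spline registration recovers identity and a synthetic bump", {
  sp <- phantom_spec(grid_shape = c(48, 48, 24), noise_sd = 0,
                     z_profile = "closed", seed = 10)
  v <- make_phantom_volume(sp)
  b0 <- register_bspline_3d(v, v, maxit = 40)
  disp0 <- autorad3d:::bspline_displacement(b0, v)
  expect_lt(max(abs(disp0) / rep(v$spacing, each = nrow(disp0))), 0.25)
  truth <- bspline_grid(v, (dim(v$voxels) - 1) * v$spacing / 8)
  ci <- round(truth$shape / 2)
  truth$coef[ci[1] + 1, ci[2], ci[3], 1] <- 30   # 3 voxels at the knot
  mv <- warp_volume(v, bspline = truth, reference = v)
  rec <- register_bspline_3d(v, mv, grid_levels = 2, maxit = 60)
  pts <- grid_points(v)
  dinv <- invert_bspline_field(truth, pts)
  drec <- autorad3d:::bspline_displacement(rec, v)
  errv <- (drec - dinv) / rep(v$spacing, each = nrow(pts))
  rms <- sqrt(mean(rowSums(errv^2)[v$mask]))
  expect_lt(rms, 0.5)
  expect_gt(attr(rec, "ncc"), attr(rec, "ncc_affine"))
})

test_that("too-fine control grids are rejected", {
  v <- make_phantom_volume(small_spec(seed = 3))
  expect_error(register_bspline_3d(v, v, grid_spacing = c(15, 15, 30)),
               "invalid-grid")
})

test_that("warp then inverse-warp round trip is accurate inside the
           eroded mask", {
  sp <- phantom_spec(grid_shape = c(48, 48, 24), noise_sd = 0,
                     z_profile = "closed", seed = 12)
  v <- smooth_gaussian(make_phantom_volume(sp), fwhm = 2 * c(10, 10, 20))
  a <- affine3d(diag(3) * 1.04, c(18, -9, 12), volume_center(v))
  fwd <- warp_volume(v, a, reference = padded_reference(v, 6L))
  back <- warp_volume(fwd, tf_inverse(a), reference = v)
  core <- v$mask & !dilate_mask(!v$mask, c(2, 2, 1))
  rng <- diff(range(v$voxels))
  rms <- sqrt(mean((back$voxels[core] - v$voxels[core])^2))
  expect_lt(rms / rng, 0.01)
})
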