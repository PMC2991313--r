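# Synthetic phantom generator: construction contracts, determinism,
# perturbation bookkeeping and the film render round trip.

test_that("noiseless phantom values stay between the structure baselines", {
  sp <- phantom_spec(grid_shape = c(64, 64, 16), noise_sd = 0,
                     structure_levels = c(shell = 50, core = 120), seed = 3)
  v <- make_phantom_volume(sp)
  inside <- v$voxels[v$mask]
  expect_gte(min(inside), 50 - 1e-9)
  expect_lte(max(inside), 120 + 1e-9)
  # plateaus of both baselines survive the edge blending
  expect_true(sum(abs(inside - 50) < 1e-9) > 100)
  expect_true(sum(abs(inside - 120) < 1e-9) > 100)
  expect_true(all(v$voxels[!v$mask] == 0))
})

test_that("phantom generation is deterministic in the seed", {
  sp <- small_spec(seed = 9, noise_sd = 4)
  v1 <- make_phantom_volume(sp)
  v2 <- make_phantom_volume(sp)
  expect_identical(v1$voxels, v2$voxels)
  v3 <- make_phantom_volume(sp, seed = 10)
  expect_false(identical(v1$voxels, v3$voxels))
})

test_that("inner-structure mean activity matches its baseline under noise", {
  lev <- c(cortex = 60, hippocampus = 120)
  sp <- phantom_spec(grid_shape = c(64, 64, 24), noise_sd = 5,
                     structure_levels = lev, seed = 21)
  v <- make_phantom_volume(sp)
  # interior of the first structure site, eroded away from blend zones
  core <- phantom_region_mask(sp, center = c(0.30, 0.20, 0),
                              semi = c(0.15, 0.11, 0.55))
  core <- core & v$mask
  n <- sum(core)
  expect_gt(n, 200)
  se <- 5 / sqrt(n)
  expect_lt(abs(mean(v$voxels[core]) - 120), 3 * se)
})

test_that("degenerate specs are rejected", {
  expect_error(phantom_spec(grid_shape = c(4, 32, 32)), "invalid-spec")
  expect_error(phantom_spec(spacing = c(0, 10, 20)), "invalid-spec")
  expect_error(phantom_spec(structure_levels = c(a = 50, b = 50)),
               "invalid-spec")
})

test_that("zero perturbation slices equal the volume planes exactly", {
  v <- make_phantom_volume(small_spec(seed = 2))
  sl <- slice_and_perturb(v, max_shift = 0, max_angle = 0, seed = 5)
  par <- sl$truth$per_section_transforms
  expect_true(all(par$tx == 0) && all(par$ty == 0) && all(par$theta == 0))
  for (k in c(1, 6, 12)) {
    expect_identical(sl$sections[[k]]$pixels, v$voxels[, , k])
  }
})

test_that("perturbation draws respect their bounds and uniform moments", {
  v <- volume3d(array(runif(24 * 24 * 150), c(24, 24, 150)),
                spacing = c(10, 10, 20))
  sl <- slice_and_perturb(v, max_shift = 20, max_angle = 6, seed = 77)
  par <- sl$truth$per_section_transforms
  expect_equal(nrow(par), 150)
  expect_true(all(abs(par$tx) <= 20) && all(abs(par$ty) <= 20))
  expect_true(all(abs(par$theta) <= 6))
  # mean of U(-a, a) ~ 0 within 3 * (a/sqrt(3)) / sqrt(n)
  tol <- 3 * (6 / sqrt(3)) / sqrt(150)
  expect_lt(abs(mean(par$theta)), tol)
})

test_that("recorded transforms are exactly those applied", {
  v <- make_phantom_volume(small_spec(seed = 4))
  sl <- slice_and_perturb(v, max_shift = 80, max_angle = 6, seed = 11)
  par <- sl$truth$per_section_transforms
  k <- 6
  ctr <- (dim(v$voxels)[1:2] - 1) * v$spacing[1:2] / 2
  tf <- rigid2d(par$tx[k], par$ty[k], par$theta[k], center = ctr)
  undone <- autorad3d:::resample_section(sl$sections[[k]], tf_inverse(tf))
  orig <- v$voxels[, , k]
  # interior comparison (resampling shrinks the valid field twice)
  m <- undone$mask
  m[c(1:6, 27:32), ] <- FALSE
  m[, c(1:6, 27:32)] <- FALSE
  expect_lt(mean(abs(undone$pixels[m] - orig[m])), 6)
})

test_that("film render-calibrate round trip stays within quantization", {
  sp <- small_spec(seed = 6, noise_sd = 2)
  v <- make_phantom_volume(sp)
  sl <- slice_and_perturb(v, max_shift = 0, max_angle = 0, seed = 1)
  f <- render_film(sl$sections, sl$truth,
                   artifact_rates = c(dust = 0, overlap = 0), seed = 2)
  expect_equal(f$n_clamped, 0L)
  curve <- fit_calibration(f$standards)
  # max slope of the activity(gray) curve bounds the quantization error
  gd <- seq(curve$valid_range[1], curve$valid_range[2], by = 0.1)
  max_slope <- max(diff(curve$fun(gd)) / diff(gd))
  k <- 6
  sec <- f$sections[[k]]
  sec$mask <- v$mask[, , k]
  cal <- apply_calibration(sec, curve)
  err <- abs(cal$pixels[sec$mask] - sl$sections[[k]]$pixels[sec$mask])
  expect_lte(max(err), max_slope * 0.5 + 1e-9)
})

test_that("dust artifacts create extra components removed by cleaning", {
  sp <- phantom_spec(grid_shape = c(48, 48, 10), noise_sd = 2, seed = 8,
                     artifact_rates = c(dust = 1, overlap = 1))
  v <- make_phantom_volume(sp)
  sl <- slice_and_perturb(v, 50, 3, seed = 3)
  f <- render_film(sl$sections, sl$truth, artifact_rates = sp$artifact_rates,
                   seed = 4)
  n_multi <- 0
  for (s in f$sections) {
    t0 <- otsu_threshold(tabulate(as.integer(s$pixels) + 1L, 256))
    fg <- s$pixels > t0
    lab <- oracle_label_cc(array(fg, c(dim(fg), 1)))
    if (max(lab) >= 2) n_multi <- n_multi + 1
  }
  expect_gte(n_multi, 8)  # dust rate 1: nearly every section has extras
})

test_that("group study bundles have the expected size and null symmetry", {
  sp <- small_spec(seed = 5, noise_sd = 2)
  st <- make_group_study(sp, n_per_group = 8, effect_size = 0,
                         seed = 3, render = FALSE)
  expect_length(st$subjects, 16)
  expect_equal(sum(vapply(st$subjects, `[[`, "", "group") == "A"), 8)
  # effect_size = 0: group means indistinguishable at gross level
  mA <- mean(vapply(st$subjects[1:8], function(s) mean(s$volume$voxels),
                    numeric(1)))
  mB <- mean(vapply(st$subjects[9:16], function(s) mean(s$volume$voxels),
                    numeric(1)))
  expect_lt(abs(mA / mB - 1), 0.05)
})

test_that("regional effect scales group B activity by 1 + effect_size", {
  sp <- study_spec(seed = 12)
  region <- phantom_region_mask(sp)
  st <- make_group_study(sp, n_per_group = 6, effect_region = region,
                         effect_size = 0.10, seed = 31, render = FALSE)
  grp <- vapply(st$subjects, `[[`, "", "group")
  mA <- mean(vapply(st$subjects[grp == "A"],
                    function(s) mean(s$volume$voxels[region]), numeric(1)))
  mB <- mean(vapply(st$subjects[grp == "B"],
                    function(s) mean(s$volume$voxels[region]), numeric(1)))
  expect_lt(abs(mB / mA - 1.10), 0.04)
})
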