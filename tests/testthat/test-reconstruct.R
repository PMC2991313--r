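# Intra-subject reconstruction: stacking semantics, NCC properties, rigid
# transform group laws, registration recovery, center-out chain behaviour.

test_that("stacking copies sections verbatim with the right geometry", {
  v <- make_phantom_volume(small_spec(seed = 1, noise_sd = 1))
  sl <- slice_and_perturb(v, 0, 0, seed = 1)
  vol <- stack_sections(sl$sections, dz = 20)
  expect_equal(dim(vol$voxels), c(32, 32, 12))
  expect_equal(vol$spacing, c(10, 10, 20))
  for (k in c(1, 7, 12)) {
    expect_identical(vol$voxels[, , k], sl$sections[[k]]$pixels)
  }
  one <- stack_sections(sl$sections[1], dz = 20)
  expect_equal(dim(one$voxels)[3], 1)
  bad <- sl$sections
  bad[[3]]$pixels <- bad[[3]]$pixels[1:16, ]
  expect_error(stack_sections(bad, 20), "heterogeneous-sections")
  gap <- sl$sections[c(1, 2, 4)]
  expect_error(stack_sections(gap, 20), "heterogeneous-sections")
})

test_that("ncc satisfies its defining identities", {
  set.seed(5)
  a <- matrix(rnorm(100 * 100), 100)
  b <- matrix(rnorm(100 * 100), 100)
  expect_equal(ncc(a, a), 1)
  expect_equal(ncc(a, 2.5 * a + 7), 1)
  expect_equal(ncc(a, -0.3 * a + 2), -1)
  expect_lt(abs(ncc(a, b)), 4 / sqrt(length(a)))
  expect_equal(ncc(a, b), ncc(b, a), tolerance = 1e-12)
  expect_error(ncc(a, matrix(1, 100, 100)), "undefined-correlation")
  m <- matrix(FALSE, 100, 100)
  expect_error(ncc(a, b, m), "undefined-correlation")
})

test_that("rigid2d compose/inverse obey the group laws", {
  set.seed(8)
  for (i in 1:25) {
    ctr <- runif(2, 0, 600)
    t1 <- rigid2d(runif(1, -100, 100), runif(1, -100, 100),
                  runif(1, -40, 40), center = ctr)
    t2 <- rigid2d(runif(1, -100, 100), runif(1, -100, 100),
                  runif(1, -40, 40), center = ctr)
    id <- tf_compose(t1, tf_inverse(t1))
    expect_lt(max(abs(c(id$tx, id$ty, id$theta))), 1e-9)
    # composition acts as sequential application on points
    pts <- matrix(runif(10, 0, 600), 5, 2)
    expect_equal(tf_apply(tf_compose(t1, t2), pts),
                 tf_apply(t1, tf_apply(t2, pts)), tolerance = 1e-9)
  }
})

test_that("self-registration returns the identity", {
  v <- make_phantom_volume(small_spec(seed = 3, noise_sd = 2))
  fx <- section_image(v$voxels[, , 6], spacing = c(10, 10), index = 5L,
                      mask = v$mask[, , 6])
  r <- register_rigid_2d(fx, fx)
  expect_lt(abs(r$tx), 5)     # 0.5 px at 10 um
  expect_lt(abs(r$ty), 5)
  expect_lt(abs(r$theta), 0.1)
})

test_that("known shift and rotation are recovered on noiseless sections", {
  v <- make_phantom_volume(small_spec(seed = 3, noise_sd = 0))
  fx <- section_image(v$voxels[, , 6], spacing = c(10, 10), index = 5L,
                      mask = v$mask[, , 6])
  ctr <- (dim(fx$pixels) - 1) * fx$spacing / 2
  tf <- rigid2d(30, -20, 0, center = ctr)
  mv <- autorad3d:::resample_section(fx, tf)
  r <- register_rigid_2d(fx, mv)
  want <- tf_inverse(tf)
  expect_lt(abs(r$tx - want$tx), 5)
  expect_lt(abs(r$ty - want$ty), 5)
  tf2 <- rigid2d(0, 0, 5, center = ctr)
  mv2 <- autorad3d:::resample_section(fx, tf2)
  r2 <- register_rigid_2d(fx, mv2)
  expect_lt(abs(r2$theta - (-5)), 0.25)
})

test_that("already-aligned stacks are a fixed point of the chain", {
  v <- make_phantom_volume(small_spec(seed = 2, noise_sd = 1))
  sl <- slice_and_perturb(v, 0, 0, seed = 1)
  vol <- stack_sections(sl$sections, dz = 20)
  al <- align_stack_center_out(vol)
  # fixed point up to the per-pair metric noise floor (sub-pixel,
  # sub-half-degree); the chain never materially degrades the stack
  for (tf in al$report$transforms) {
    expect_lt(max(abs(c(tf$tx, tf$ty))), 5.5)
    expect_lt(abs(tf$theta), 0.5)
  }
  expect_gt(stack_adjacent_ncc(al$volume),
            stack_adjacent_ncc(vol) - 0.01)
})

test_that("center-out alignment undoes perturbations and never
           degrades the pair metric", {
  sp <- phantom_spec(grid_shape = c(48, 48, 14), seed = 17)
  v <- make_phantom_volume(sp)
  sl <- slice_and_perturb(v, max_shift = 60, max_angle = 4, seed = 18)
  vol <- stack_sections(sl$sections, dz = 20)
  al <- align_stack_center_out(vol)
  # anchor convention: 0-based floor(N/2) - 1
  expect_identical(al$report$anchor, 6L)
  # optimizer never returns worse than its initialization
  expect_true(all(al$report$pairs$ncc_after >=
                    al$report$pairs$ncc_before - 1e-4))
  expect_gt(stack_adjacent_ncc(al$volume), stack_adjacent_ncc(vol))
  ctr <- (dim(v$voxels)[1:2] - 1) * v$spacing[1:2] / 2
  res <- alignment_residuals(sl$truth$per_section_transforms,
                             al$report$transforms, al$report$anchor, ctr)
  expect_lt(max(abs(res[, 1:2])), 10)   # 1 px
  expect_lt(max(abs(res[, 3])), 0.5)
})
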