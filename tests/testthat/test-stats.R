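# Voxel-wise statistics: t-test against hand computation and t.test(),
# signed p-maps, BH and FWE against definitional oracles, clustering
# against flood fill, smoothing variance reduction.

make_gd <- function(arrs, labels, spacing = c(10, 10, 20)) {
  group_data(lapply(arrs, function(a) volume3d(a, spacing = spacing)),
             labels)
}

test_that("pooled t matches the long-hand computation at a single voxel", {
  # A = {10, 12, 11}, B = {14, 15, 16}: means 11 and 15, both variances 1,
  # pooled s2 = 1, t = 4 / sqrt(2/3) = 4.898979..., df = 4
  vals <- c(10, 12, 11, 14, 15, 16)
  arrs <- lapply(vals, function(x) {
    a <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
    a[3, 3, 2] <- x
    a
  })
  gd <- make_gd(arrs, c("A", "A", "A", "B", "B", "B"))
  m <- voxelwise_ttest(gd)
  expect_equal(m$t_map[3, 3, 2], 4.898979485, tolerance = 1e-8)
  expect_identical(m$df, 4L + 0)
  tt <- t.test(vals[4:6], vals[1:3], var.equal = TRUE)
  expect_equal(m$t_map[3, 3, 2], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(2 * min(m$p_pos[3, 3, 2], m$p_neg[3, 3, 2]),
               tt$p.value, tolerance = 1e-10)
})

test_that("identical groups give t = 0 and one-sided p = 0.5", {
  set.seed(31)
  a <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  gd <- make_gd(list(a, a + 0, a, a), c("A", "B", "A", "B"))
  suppressWarnings(m <- voxelwise_ttest(gd))
  nz <- m$mask
  expect_true(all(abs(m$t_map[nz]) < 1e-12))
  expect_true(all(abs(m$p_pos[nz] - 0.5) < 1e-12))
})

test_that("swapping labels negates t and swaps the signed p-maps", {
  set.seed(32)
  arrs <- replicate(8, array(rnorm(8 * 8 * 4), c(8, 8, 4)),
                    simplify = FALSE)
  labs <- rep(c("A", "B"), each = 4)
  m1 <- voxelwise_ttest(make_gd(arrs, labs))
  m2 <- voxelwise_ttest(make_gd(arrs, rev(labs)))
  expect_equal(m1$t_map, -m2$t_map, tolerance = 1e-12)
  expect_equal(m1$p_pos, m2$p_neg, tolerance = 1e-12)
  expect_equal(m1$p_neg, m2$p_pos, tolerance = 1e-12)
})

test_that("constant voxels are excluded as degenerate, not given p = 1", {
  set.seed(33)
  arrs <- replicate(6, array(rnorm(6 * 6 * 2), c(6, 6, 2)),
                    simplify = FALSE)
  for (i in seq_along(arrs)) arrs[[i]][2, 2, 1] <- 7
  m <- voxelwise_ttest(make_gd(arrs, rep(c("A", "B"), 3)))
  expect_identical(m$n_degenerate, 1L)
  expect_true(is.na(m$t_map[2, 2, 1]))
  expect_false(m$mask[2, 2, 1])
})

test_that("BH step-up equals its definition on toy vectors", {
  p <- array(c(0.01, 0.02, 0.03, 0.04, 0.9), c(5, 1, 1))
  r <- fdr_bh(p, q = 0.05)
  expect_equal(r$threshold, 0.04)
  expect_identical(r$n_discoveries, 4L)
  expect_equal(as.numeric(r$q_map[, 1, 1]),
               p.adjust(c(0.01, 0.02, 0.03, 0.04, 0.9), "BH"))
  r1 <- fdr_bh(array(1, c(4, 1, 1)), q = 0.05)
  expect_identical(r1$n_discoveries, 0L)
  expect_true(is.na(r1$threshold))
  # single test: BH reduces to p <= q
  expect_identical(fdr_bh(array(0.04, c(1, 1, 1)), q = 0.05)$n_discoveries,
                   1L)
  expect_identical(fdr_bh(array(0.06, c(1, 1, 1)), q = 0.05)$n_discoveries,
                   0L)
})

test_that("BH on random p-vectors equals a direct step-up evaluation", {
  set.seed(9)
  for (i in 1:20) {
    m <- sample(5:400, 1)
    pv <- runif(m)^sample(1:3, 1)
    r <- fdr_bh(array(pv, c(m, 1, 1)), q = 0.1)
    ps <- sort(pv)
    ok <- which(ps <= seq_len(m) * 0.1 / m)
    want <- if (length(ok)) sum(pv <= ps[max(ok)]) else 0L
    expect_identical(r$n_discoveries, as.integer(want))
  }
})

test_that("bonferroni map multiplies by m and dominates BH", {
  set.seed(41)
  arrs <- replicate(8, array(rnorm(10 * 10 * 4), c(10, 10, 4)),
                    simplify = FALSE)
  gd <- make_gd(arrs, rep(c("A", "B"), each = 4))
  m <- voxelwise_ttest(gd)
  fwe <- fwe_correct(m, alpha = 0.05, method = "bonferroni")
  p2 <- 2 * pmin(m$p_pos, m$p_neg)
  nm <- sum(m$mask)
  expect_equal(fwe$p_fwe_map[m$mask], pmin(1, nm * p2[m$mask]),
               tolerance = 1e-12)
  q <- fdr_bh(p2, m$mask, 0.05)
  expect_true(all(fwe$p_fwe_map[m$mask] >= q$q_map[m$mask] - 1e-12))
})

test_that("exhaustive 3-vs-3 permutation max-T equals direct enumeration", {
  set.seed(17)
  arrs <- replicate(6, array(rnorm(5 * 5 * 2), c(5, 5, 2)),
                    simplify = FALSE)
  labs <- rep(c("A", "B"), 3)
  gd <- make_gd(arrs, labs)
  m <- voxelwise_ttest(gd)
  fwe <- fwe_correct(m, data = gd, alpha = 0.05,
                     method = "permutation_maxT", n_perm = 1000)
  expect_identical(fwe$n_perm_used, 20L)   # choose(6, 3)
  # oracle: enumerate every relabeling, recompute t by t.test
  X <- sapply(arrs, function(a) as.numeric(a))
  combs <- combn(6, 3)
  maxT <- apply(combs, 2, function(ia) {
    max(abs(apply(X, 1, function(row) {
      t.test(row[-ia], row[ia], var.equal = TRUE)$statistic
    })))
  })
  tobs <- abs(m$t_map[m$mask])
  want <- vapply(tobs, function(t0) sum(maxT >= t0 - 1e-12) / 20,
                 numeric(1))
  expect_equal(as.numeric(fwe$p_fwe_map[m$mask]), want, tolerance = 1e-10)
})

test_that("cluster filtering matches flood fill and applies size cuts", {
  r0 <- cluster_filter(array(FALSE, c(6, 6, 4)))
  expect_identical(nrow(r0$table), 0L)
  m <- array(FALSE, c(20, 20, 6))
  m[2:11, 2:11, 2:3] <- TRUE          # 200 voxels
  m[15:19, 15:19, 5] <- FALSE
  m[16, 16, 5] <- TRUE; m[17, 17, 5] <- TRUE  # diagonal pair: size 2
  r <- cluster_filter(m, min_cluster_size = 10)
  expect_identical(nrow(r$table), 1L)
  expect_identical(r$table$size, 200L)
  set.seed(23)
  for (i in 1:25) {
    d <- c(sample(5:14, 1), sample(5:14, 1), sample(3:8, 1))
    bm <- array(runif(prod(d)) < 0.25, d)
    r <- cluster_filter(bm, min_cluster_size = 1)
    expect_identical(cc_sizes(r$labels), cc_sizes(oracle_label_cc(bm)))
  }
})

test_that("cluster table is sorted by size with correct peak lookup", {
  m <- array(FALSE, c(15, 15, 4))
  m[2:4, 2:4, 2] <- TRUE     # 9 voxels
  m[8:13, 8:13, 2:3] <- TRUE # 72 voxels
  stat <- array(0, dim(m))
  stat[10, 9, 3] <- -9.5
  stat[3, 3, 2] <- 4.2
  r <- cluster_filter(m, min_cluster_size = 1, stat_map = stat)
  expect_identical(r$table$size, c(72L, 9L))
  expect_equal(r$table$peak_stat[1], -9.5)
  expect_identical(unlist(r$table[1, c("peak_x", "peak_y", "peak_z")],
                          use.names = FALSE), c(10L, 9L, 3L))
})

test_that("smoothing reduces white-noise variance by the kernel energy", {
  set.seed(51)
  d <- c(48, 48, 24)
  v <- volume3d(array(rnorm(prod(d)), d), spacing = c(10, 10, 20))
  sm <- smooth_gaussian(v, fwhm = 3 * v$spacing)
  core <- array(FALSE, d)
  core[9:40, 9:40, 6:19] <- TRUE
  ratio <- var(sm$voxels[core]) / var(v$voxels[core])
  # separable kernel: variance ratio = prod(sum(k_axis^2))
  want <- prod(vapply(3 * v$spacing / (2 * sqrt(2 * log(2))) / v$spacing,
                      function(s) sum(autorad3d:::gauss_kernel(s)^2),
                      numeric(1)))
  expect_lt(abs(ratio / want - 1), 0.10)
})

test_that("global scaling removes a pure global imbalance", {
  set.seed(61)
  base <- array(rnorm(8 * 8 * 4, 100, 5), c(8, 8, 4))
  arrs <- c(lapply(1:4, function(i) base + rnorm(length(base))),
            lapply(1:4, function(i) 1.2 * (base + rnorm(length(base)))))
  gd <- make_gd(arrs, rep(c("A", "B"), each = 4))
  m_raw <- voxelwise_ttest(gd)
  m_sc <- voxelwise_ttest(scale_global(gd))
  expect_gt(mean(abs(m_raw$t_map[m_raw$mask])),
            10 * mean(abs(m_sc$t_map[m_sc$mask])))
})
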