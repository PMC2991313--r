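# Section cleaning: Otsu thresholding against the brute-force oracle,
# morphological cleaning contracts, batch behaviour.

test_that("otsu matches exhaustive between-class variance maximization", {
  set.seed(42)
  for (i in 1:40) {
    h <- integer(256)
    # random bimodal-ish histograms plus degenerate-ish shapes
    n1 <- sample(50:5000, 1)
    n2 <- sample(50:5000, 1)
    m1 <- sample(0:120, 1)
    m2 <- sample(130:255, 1)
    h1 <- table(pmin(pmax(round(rnorm(n1, m1, sample(3:30, 1))), 0), 255))
    h2 <- table(pmin(pmax(round(rnorm(n2, m2, sample(3:30, 1))), 0), 255))
    h[as.integer(names(h1)) + 1] <- h[as.integer(names(h1)) + 1] + c(h1)
    h[as.integer(names(h2)) + 1] <- h[as.integer(names(h2)) + 1] + c(h2)
    expect_identical(otsu_threshold(h), oracle_otsu(h))
  }
})

test_that("otsu two-point histograms separate perfectly, ties to lowest t", {
  h <- integer(256)
  h[10 + 1] <- 100
  h[200 + 1] <- 100
  t <- otsu_threshold(h)
  expect_identical(t, oracle_otsu(h))
  expect_identical(t, 10L)   # every t in [10, 199] is optimal; lowest wins
  # closed form for equal masses at 0 and 255
  h2 <- integer(256)
  h2[0 + 1] <- 500
  h2[255 + 1] <- 500
  g <- 0:255
  w0 <- cumsum(h2) / sum(h2)
  s0 <- cumsum(h2 * g) / sum(h2)
  s2 <- ((s0[256] * w0 - s0)^2 / (w0 * (1 - w0)))[1:255]
  expect_equal(max(s2, na.rm = TRUE), 0.25 * 255^2)
  expect_identical(otsu_threshold(h2), 0L)
})

test_that("degenerate histograms error", {
  h <- integer(256)
  h[50] <- 1000
  expect_error(otsu_threshold(h), "degenerate-histogram")
})

test_that("cleaning keeps one component and removes small artifacts", {
  px <- matrix(10L, 64, 64)
  px[20:45, 18:40] <- 180L                    # tissue block
  px[5:6, 5:6] <- 250L                        # dust speckle (sub-element)
  px[55:60, 50:58] <- 170L                    # disjoint smaller overlap blob
  sec <- section_image(px, spacing = c(10, 10), index = 0L)
  cleaned <- clean_section(sec, cleaning_params(opening_radius = 30,
                                                min_component_pixels = 10))
  lab <- oracle_label_cc(array(cleaned$mask, c(64, 64, 1)))
  expect_identical(max(lab), 1L)
  expect_false(any(cleaned$mask[5:6, 5:6]))
  expect_false(any(cleaned$mask[55:60, 50:58]))
  expect_true(all(cleaned$mask[25:40, 22:36]))
  expect_true(all(cleaned$pixels[!cleaned$mask] == 0))
})

test_that("largest component is selected by area, as the oracle computes", {
  px <- matrix(0L, 48, 48)
  px[5:30, 5:30] <- 200L     # area 676
  px[36:46, 36:46] <- 200L   # area 121
  sec <- section_image(px, spacing = c(10, 10), index = 3L)
  cleaned <- clean_section(sec, cleaning_params(opening_radius = 0))
  sizes <- cc_sizes(oracle_label_cc(array(px > 100, c(48, 48, 1))))
  expect_identical(sum(cleaned$mask), as.integer(max(sizes)))
  expect_true(all(cleaned$mask[5:30, 5:30]))
})

test_that("cleaning is idempotent and never grows the foreground", {
  sp <- small_spec(seed = 13, noise_sd = 3,
                   artifact_rates = c(dust = 1, overlap = 0.5))
  v <- make_phantom_volume(sp)
  sl <- slice_and_perturb(v, 40, 3, seed = 2)
  f <- render_film(sl$sections, sl$truth, artifact_rates = sp$artifact_rates,
                   seed = 6)
  cp <- cleaning_params(opening_radius = 20, min_component_pixels = 10)
  for (k in c(3, 6, 9)) {
    c1 <- clean_section(f$sections[[k]], cp)
    t0 <- otsu_threshold(tabulate(as.integer(f$sections[[k]]$pixels) + 1L,
                                  256))
    expect_lte(sum(c1$mask), sum(f$sections[[k]]$pixels > t0))
    c2 <- clean_section(c1, cp)
    expect_identical(c2$mask, c1$mask)
  }
})

test_that("clean_subject preserves order and aborts listing bad indices", {
  sp <- small_spec(seed = 14, noise_sd = 2)
  v <- make_phantom_volume(sp)
  sl <- slice_and_perturb(v, 30, 2, seed = 3)
  f <- render_film(sl$sections, sl$truth, seed = 4)
  cp <- cleaning_params(opening_radius = 20, min_component_pixels = 10)
  cleaned <- clean_subject(f$sections, cp)
  expect_identical(vapply(cleaned, `[[`, 0L, "index"), 0:11)
  for (cs in cleaned) {
    expect_identical(max(oracle_label_cc(array(cs$mask, c(32, 32, 1)))), 1L)
  }
  bad <- f$sections
  bad[[4]] <- section_image(matrix(7L, 32, 32), spacing = c(10, 10),
                            index = 3L)
  expect_error(clean_subject(bad, cp), "3")
})
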