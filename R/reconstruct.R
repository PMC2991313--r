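# Intra-subject 3D reconstruction: calibrated sections are stacked along z
# and sequentially realigned, starting from the two central sections and
# proceeding outward, each section registered to its already-aligned inner
# neighbour with an in-plane rigid transform maximizing normalized
# cross-correlation. Registration runs first on x4-downsampled sections,
# then refines at full resolution.

#' Stack sections into a volume
#'
#' @param sections list of `section_image`s with identical shape and
#'   in-plane spacing and contiguous indices.
#' @param dz inter-section spacing in micrometres.
#' @return A `volume3d` with slice `k` equal to section `k`; the volume mask
#'   stacks the section masks (all-true where a section has none).
#' @export
stack_sections <- function(sections, dz = 20) {
  stopifnot(length(sections) >= 1, dz > 0)
  sections <- sections[order(vapply(sections, `[[`, 0L, "index"))]
  idx <- vapply(sections, `[[`, 0L, "index")
  if (!all(diff(idx) == 1)) {
    stop("heterogeneous-sections: indices not contiguous")
  }
  d1 <- dim(sections[[1]]$pixels)
  sp <- sections[[1]]$spacing
  for (s in sections) {
    if (!all(dim(s$pixels) == d1) || !all(s$spacing == sp)) {
      stop("heterogeneous-sections: shape or spacing mismatch")
    }
  }
  n <- length(sections)
  vox <- array(0, c(d1, n))
  msk <- array(TRUE, c(d1, n))
  for (k in seq_len(n)) {
    vox[, , k] <- sections[[k]]$pixels
    if (!is.null(sections[[k]]$mask)) msk[, , k] <- sections[[k]]$mask
  }
  volume3d(vox, spacing = c(sp, dz), mask = msk)
}

#' Normalized cross-correlation of two images
#'
#' `sum((a - mean a)(b - mean b)) / sqrt(sum((a - mean a)^2) sum((b - mean
#' b)^2))` over the joint mask; the registration cost is its negative. Lies
#' in `[-1, 1]` and is invariant to positive affine intensity changes.
#'
#' @param a,b numeric matrices or arrays of identical shape.
#' @param joint_mask logical array of the same shape, or `NULL` for all.
#' @return The NCC score.
#' @export
ncc <- function(a, b, joint_mask = NULL) {
  stopifnot(all(dim(a) == dim(b)))
  if (is.null(joint_mask)) {
    x <- as.numeric(a); y <- as.numeric(b)
  } else {
    stopifnot(all(dim(joint_mask) == dim(a)))
    x <- a[joint_mask]; y <- b[joint_mask]
  }
  if (length(x) == 0) stop("undefined-correlation: empty joint mask")
  x <- x - mean(x); y <- y - mean(y)
  den <- sqrt(sum(x^2) * sum(y^2))
  if (den == 0) stop("undefined-correlation: zero variance inside mask")
  sum(x * y) / den
}

# NCC of fixed section vs moving section resampled under tf. The metric
# region is the fixed-image mask intersected with the moving field of view
# (ITK's fixed-mask convention): unlike a joint tissue mask, it varies
# continuously with the transform, so the cost surface has no
# mask-quantization jumps. Background zeros of the moving section count as
# signal, anchoring the tissue outline.
section_pair_ncc <- function(fixed, moving, tf) {
  moving$mask <- NULL
  r <- resample_section(moving, tf)
  m <- r$mask                     # in-field indicator
  if (!is.null(fixed$mask)) m <- m & fixed$mask
  if (sum(m) < 16) return(NA_real_)
  tryCatch(ncc(fixed$pixels, r$pixels, m), error = function(e) NA_real_)
}

#' Rigid in-plane registration of two sections
#'
#' Two-stage optimization of the 3-parameter in-plane rigid transform
#' (translation in um, rotation in degrees about the section center)
#' maximizing masked NCC: (1) a deterministic coarse translation search
#' plus simplex refinement on sections downsampled by `downsample`, (2)
#' simplex refinement at full resolution (skipped when
#' `refine_full = FALSE`). Deterministic given its inputs. If no candidate
#' improves on `init`, `init` is returned with `converged = FALSE`.
#'
#' @param fixed,moving `section_image`s of identical geometry.
#' @param init initial `rigid2d` transform.
#' @param downsample integer reduction factor for the coarse stage.
#' @param refine_full refine at full resolution after the coarse stage?
#' @return A `rigid2d` with attributes `ncc` (final score), `ncc_init`, and
#'   `converged`.
#' @export
register_rigid_2d <- function(fixed, moving, init = NULL, downsample = 4,
                              refine_full = TRUE) {
  stopifnot(inherits(fixed, "section_image"),
            inherits(moving, "section_image"), downsample >= 1)
  ctr <- section_center(fixed)
  if (is.null(init)) init <- rigid2d(center = ctr)
  init$center <- ctr
  # metric images: lightly smoothed (noise suppression without moving the
  # optimum of the smooth content) and with the fixed mask dilated so both
  # sides of the tissue outline contribute to the metric
  smooth2d <- function(px) {
    k <- gauss_kernel(1.2)
    conv1d_axis(conv1d_axis(px, k, 1), k, 2)
  }
  fixed_m <- fixed
  fixed_m$pixels <- smooth2d(fixed$pixels)
  if (!is.null(fixed$mask)) {
    fixed_m$mask <- EBImage::dilate(
      matrix(as.numeric(fixed$mask), nrow(fixed$mask)),
      EBImage::makeBrush(9, "disc")) > 0.5
  }
  moving_m <- moving
  moving_m$pixels <- smooth2d(moving$pixels)
  moving_m$mask <- NULL
  fc <- downsample_section(fixed_m, downsample)
  mc <- downsample_section(moving_m, downsample)
  cost_for <- function(fim, mim) {
    fmask <- if (is.null(fim$mask)) matrix(FALSE, 0, 0) else fim$mask
    function(p) {
      s <- cpp_ncc_rigid2d(fim$pixels, fmask, mim$pixels, p[1], p[2],
                           p[3] * pi / 180, ctr[1], ctr[2],
                           fim$spacing[1], fim$spacing[2])
      if (is.na(s)) 2 else -s
    }
  }
  cost_c <- cost_for(fc, mc)
  p0 <- c(init$tx, init$ty, init$theta)
  # deterministic coarse search around init: one-coarse-pixel translation
  # steps and a few rotation offsets, then simplex from the best cell
  step <- fc$spacing[1]
  grid <- expand.grid(dx = -5:5 * step, dy = -5:5 * step,
                      dth = c(-8, -4, 0, 4, 8))
  cand <- cbind(p0[1] + grid$dx, p0[2] + grid$dy, p0[3] + grid$dth)
  sc <- apply(cand, 1, cost_c)
  best <- cand[which.min(sc), ]
  opt <- optim(best, cost_c, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-10,
                              parscale = c(step, step, 2)))
  p <- opt$par
  if (refine_full && downsample > 1) {
    opt2 <- optim(p, cost_for(fixed_m, moving_m), method = "Nelder-Mead",
                  control = list(maxit = 300, reltol = 1e-10,
                                 parscale = c(fixed$spacing[1],
                                              fixed$spacing[1], 0.25)))
    p <- opt2$par
  }
  ncc_init <- section_pair_ncc(fixed_m, moving_m, init)
  ncc_fin <- section_pair_ncc(fixed_m, moving_m,
                              rigid2d(p[1], p[2], p[3], center = ctr))
  converged <- !is.na(ncc_fin) &&
    (is.na(ncc_init) || ncc_fin >= ncc_init - 1e-12)
  if (!converged) {
    p <- c(init$tx, init$ty, init$theta)
    ncc_fin <- ncc_init
  }
  out <- rigid2d(p[1], p[2], p[3], center = ctr)
  attr(out, "ncc") <- ncc_fin
  attr(out, "ncc_init") <- ncc_init
  attr(out, "converged") <- converged
  out
}

#' Center-out sequential alignment of a section stack
#'
#' With `N` sections (0-based indices), the two central sections
#' `c0 = floor(N/2) - 1` and `c1 = floor(N/2)` are registered first: `c1` is
#' moved onto `c0`, which anchors the global frame (the global pose of a
#' sequential reconstruction is arbitrary). Alignment then proceeds outward
#' in both directions, each section registered to its already-aligned inner
#' neighbour and initialized from that neighbour's final transform, which
#' tracks slowly varying mounting error. Resampled sections replace the
#' slices of the output volume.
#'
#' @param volume a `volume3d` stack (depth `>= 2`).
#' @param downsample,refine_full passed to [register_rigid_2d()].
#' @return List with `volume` (realigned) and `report` (class
#'   `alignment_report`): per-pair NCC before (at the chained
#'   initialization) and after optimization, per-section `rigid2d`
#'   transforms into the anchor frame, and convergence flags.
#' @export
align_stack_center_out <- function(volume, downsample = 4,
                                   refine_full = TRUE) {
  stopifnot(inherits(volume, "volume3d"))
  d <- dim(volume$voxels)
  n <- d[3]
  if (n < 2) stop("need at least 2 sections to align")
  get_sec <- function(k) {
    section_image(volume$voxels[, , k], spacing = volume$spacing[1:2],
                  index = k - 1L, mask = volume$mask[, , k])
  }
  ctr <- section_center(get_sec(1))
  c0 <- as.integer(floor(n / 2))   # 1-based; 0-based anchor is c0 - 1
  c1 <- c0 + 1L
  out_vox <- volume$voxels
  out_msk <- volume$mask
  transforms <- rep(list(rigid2d(center = ctr)), n)
  aligned <- vector("list", n)
  aligned[[c0]] <- get_sec(c0)
  pair_rows <- list()
  do_pair <- function(fixed_k, moving_k, init) {
    fixed <- aligned[[fixed_k]]
    moving <- get_sec(moving_k)
    tf <- register_rigid_2d(fixed, moving, init = init,
                            downsample = downsample,
                            refine_full = refine_full)
    res <- resample_section(moving, tf)
    aligned[[moving_k]] <<- res
    out_vox[, , moving_k] <<- res$pixels
    out_msk[, , moving_k] <<- res$mask
    transforms[[moving_k]] <<- tf
    pair_rows[[length(pair_rows) + 1]] <<- data.frame(
      fixed = fixed_k - 1L, moving = moving_k - 1L,
      ncc_before = attr(tf, "ncc_init"), ncc_after = attr(tf, "ncc"),
      converged = attr(tf, "converged"))
    tf
  }
  tf <- do_pair(c0, c1, rigid2d(center = ctr))
  if (c1 < n) {
    for (k in (c1 + 1):n) tf <- do_pair(k - 1, k, tf)
  }
  tf <- transforms[[c0]]
  if (c0 > 1) {
    for (k in (c0 - 1):1) tf <- do_pair(k + 1, k, tf)
  }
  report <- structure(
    list(pairs = do.call(rbind, pair_rows), transforms = transforms,
         anchor = c0 - 1L),
    class = "alignment_report")
  list(volume = volume3d(out_vox, spacing = volume$spacing, mask = out_msk,
                         origin = volume$origin),
       report = report)
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf(
    "<alignment_report> %d pairs, anchor section %d, mean NCC %.4f -> %.4f, %d converged\n",
    nrow(x$pairs), x$anchor, mean(x$pairs$ncc_before, na.rm = TRUE),
    mean(x$pairs$ncc_after, na.rm = TRUE), sum(x$pairs$converged)))
  invisible(x)
}

#' Mean adjacent-pair NCC of a stack
#'
#' Quality summary used to check that alignment never degrades a stack.
#'
#' @param volume a `volume3d`.
#' @return Mean NCC over all adjacent slice pairs with a valid joint mask.
#' @export
stack_adjacent_ncc <- function(volume) {
  d <- dim(volume$voxels)
  vals <- vapply(seq_len(d[3] - 1), function(k) {
    m <- volume$mask[, , k] & volume$mask[, , k + 1]
    if (sum(m) < 16) return(NA_real_)
    tryCatch(ncc(volume$voxels[, , k], volume$voxels[, , k + 1], m),
             error = function(e) NA_real_)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}
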