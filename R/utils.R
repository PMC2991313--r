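# Shared internal helpers: seeded RNG scoping, resampling wrappers,
# block-mean pyramids and separable convolution.

# Run expr with a local RNG state seeded from `seed`; the caller's RNG
# stream is untouched. All stochastic package code funnels through this.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Resample a section under a rigid2d map (backward mapping, bilinear pixels,
# nearest-neighbour mask). Out-of-field pixels are 0 and masked out.
resample_section <- function(section, tf) {
  stopifnot(inherits(section, "section_image"), inherits(tf, "rigid2d"))
  mask <- section$mask
  if (is.null(mask)) mask <- matrix(TRUE, 0, 0)
  r <- cpp_resample_rigid2d(section$pixels, mask, tf$tx, tf$ty,
                            tf$theta * pi / 180, tf$center[1], tf$center[2],
                            section$spacing[1], section$spacing[2])
  section_image(r$pixels, spacing = section$spacing, index = section$index,
                mask = r$mask)
}

# Resample a volume under affine (+ optional B-spline displacement) onto the
# grid of `reference`. Linear interpolation for voxels, NN for the mask.
resample_volume <- function(volume, affine = NULL, bspline = NULL,
                            reference = volume) {
  stopifnot(inherits(volume, "volume3d"), inherits(reference, "volume3d"))
  if (is.null(affine)) {
    affine <- affine3d(center = volume_center(reference))
  }
  disp <- if (is.null(bspline)) matrix(0, 0, 3) else
    bspline_displacement(bspline, reference)
  r <- cpp_resample_3d(volume$voxels, volume$mask, dim(volume$voxels),
                       volume$spacing, volume$origin,
                       as.numeric(affine$matrix), affine$translation,
                       affine$center, dim(reference$voxels),
                       reference$spacing, reference$origin, disp)
  volume3d(r$voxels, spacing = reference$spacing, mask = r$mask,
           origin = reference$origin)
}

# Integer-factor block-mean downsampling of a section (pixels averaged,
# mask kept where >= half the block is tissue).
downsample_section <- function(section, factor) {
  if (factor <= 1) return(section)
  p <- block_mean_2d(section$pixels, factor)
  m <- NULL
  if (!is.null(section$mask)) {
    m <- block_mean_2d(section$mask * 1, factor) >= 0.5
  }
  section_image(p, spacing = section$spacing * factor,
                index = section$index, mask = m)
}

block_mean_2d <- function(m, f) {
  nx <- floor(nrow(m) / f) * f
  ny <- floor(ncol(m) / f) * f
  m <- m[seq_len(nx), seq_len(ny), drop = FALSE]
  a <- array(m, c(f, nx / f, f, ny / f))
  apply(a, c(2, 4), mean)
}

block_mean_3d <- function(a, f) {
  d <- floor(dim(a) / f) * f
  a <- a[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  b <- array(a, c(f, d[1] / f, f, d[2] / f, f, d[3] / f))
  apply(b, c(2, 4, 6), mean)
}

downsample_volume <- function(volume, factor) {
  if (factor <= 1) return(volume)
  v <- block_mean_3d(volume$voxels, factor)
  m <- block_mean_3d(volume$mask * 1, factor) >= 0.5
  volume3d(v, spacing = volume$spacing * factor, mask = m,
           origin = volume$origin + (factor - 1) * volume$spacing / 2)
}

# 1D convolution of a 2D/3D array along `axis` with a short symmetric
# kernel, zero padding at the ends; shift-and-add over kernel taps.
conv1d_axis <- function(a, kernel, axis) {
  d <- dim(a)
  r <- (length(kernel) - 1) / 2
  n <- d[axis]
  out <- array(0, d)
  nd <- length(d)
  for (m in seq_along(kernel)) {
    off <- m - 1 - r
    dst <- max(1, 1 - off):min(n, n - off)
    if (length(dst) == 0 || dst[1] > dst[length(dst)]) next
    src <- dst + off
    k <- kernel[m]
    if (nd == 2) {
      if (axis == 1) out[dst, ] <- out[dst, ] + k * a[src, ]
      else out[, dst] <- out[, dst] + k * a[, src]
    } else {
      if (axis == 1) out[dst, , ] <- out[dst, , ] + k * a[src, , ]
      else if (axis == 2) out[, dst, ] <- out[, dst, ] + k * a[, src, ]
      else out[, , dst] <- out[, , dst] + k * a[, , src]
    }
  }
  out
}

gauss_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  k <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' Dilate a 3D binary mask
#'
#' Morphological dilation with an ellipsoidal structuring element measured
#' in voxels per axis (so anisotropic grids can use an isotropic physical
#' radius). Used e.g. to put a guard band around a known activation region
#' when counting false discoveries in smoothed maps.
#'
#' @param mask logical 3D array.
#' @param radius integer radius in voxels, length 1 (recycled) or 3.
#' @return Dilated logical array.
#' @export
dilate_mask <- function(mask, radius) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3, all(radius >= 0))
  r <- rep(as.integer(radius), length.out = 3)
  d <- dim(mask)
  out <- mask
  for (dx in -r[1]:r[1]) for (dy in -r[2]:r[2]) for (dz in -r[3]:r[3]) {
    if (sum((c(dx, dy, dz) / pmax(r, 1))^2 * (r > 0)) > 1) next
    if (dx == 0 && dy == 0 && dz == 0) next
    xs <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
    ys <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
    zs <- pmin(pmax(seq_len(d[3]) + dz, 1), d[3])
    out <- out | mask[xs, ys, zs]
  }
  out
}

# Pad a volume by replicating its boundary voxels (and mask), shifting the
# origin so physical coordinates are preserved.
pad_volume_edges <- function(volume, pad) {
  d <- dim(volume$voxels)
  ix <- pmin(pmax(seq_len(d[1] + 2 * pad[1]) - pad[1], 1), d[1])
  iy <- pmin(pmax(seq_len(d[2] + 2 * pad[2]) - pad[2], 1), d[2])
  iz <- pmin(pmax(seq_len(d[3] + 2 * pad[3]) - pad[3], 1), d[3])
  volume3d(volume$voxels[ix, iy, iz], spacing = volume$spacing,
           mask = volume$mask[ix, iy, iz],
           origin = volume$origin - pad * volume$spacing)
}
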