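# Shared fixtures and measurement helpers for the test suite. Everything is
# generated in code at fixed seeds; nothing is read from disk.

small_spec <- function(seed = 1L, noise_sd = 0, ...) {
  phantom_spec(grid_shape = c(32, 32, 12), noise_sd = noise_sd, seed = seed,
               ...)
}

study_spec <- function(seed = 1L, ...) {
  phantom_spec(grid_shape = c(64, 64, 40), seed = seed, ...)
}

# Residual of a recovered section transform against ground truth, after
# removing the global frame ambiguity (anchor transform A): the composition
# A^-1 o T_k o R_k should be the identity.
alignment_residuals <- function(truth_par, transforms, anchor0, center) {
  a <- anchor0 + 1
  A <- rigid2d(truth_par$tx[a], truth_par$ty[a], truth_par$theta[a],
               center = center)
  t(vapply(seq_len(nrow(truth_par)), function(k) {
    Tk <- rigid2d(truth_par$tx[k], truth_par$ty[k], truth_par$theta[k],
                  center = center)
    D <- tf_compose(tf_inverse(A), tf_compose(Tk, transforms[[k]]))
    c(tx = D$tx, ty = D$ty, theta = D$theta)
  }, numeric(3)))
}

# Scale / rotation / translation discrepancy between two affines via SVD
# polar decomposition.
affine_errors <- function(rec, truth) {
  sv <- svd(rec$matrix)
  svt <- svd(truth$matrix)
  rot_r <- sv$u %*% t(sv$v)
  rot_t <- svt$u %*% t(svt$v)
  ang <- acos(min(1, max(-1, (sum(diag(t(rot_r) %*% rot_t)) - 1) / 2)))
  list(scale_pct = 100 * max(abs(sv$d / svt$d - 1)),
       rot_deg = ang * 180 / pi,
       trans_um = max(abs(rec$translation - truth$translation)))
}

# Reference canvas with z padding, used when a synthetic 3D transform may
# push content beyond the source field of view.
padded_reference <- function(volume, pad_z = 8L) {
  d <- dim(volume$voxels)
  volume3d(array(0, d + c(0L, 0L, 2L * pad_z)), spacing = volume$spacing,
           origin = volume$origin - c(0, 0, pad_z * volume$spacing[3]))
}

# Exact inverse displacement of a B-spline field at given points, by
# fixed-point iteration on D_inv(x) = -D(x + D_inv(x)).
invert_bspline_field <- function(tf, pts, iters = 15) {
  dinv <- matrix(0, nrow(pts), 3)
  for (i in seq_len(iters)) {
    dinv <- -autorad3d:::bspline_eval_points(tf, pts + dinv)
  }
  dinv
}

grid_points <- function(volume) {
  d <- dim(volume$voxels)
  as.matrix(expand.grid(
    volume$origin[1] + (0:(d[1] - 1)) * volume$spacing[1],
    volume$origin[2] + (0:(d[2] - 1)) * volume$spacing[2],
    volume$origin[3] + (0:(d[3] - 1)) * volume$spacing[3]))
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
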