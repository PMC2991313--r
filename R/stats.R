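# Voxel-wise group statistics on spatially normalized volumes: Gaussian
# smoothing, pooled two-sample t-maps with signed one-sided p-maps, FWE
# (Bonferroni or permutation max-T) and FDR (Benjamini-Hochberg) control,
# and 26-connected cluster-size filtering.

#' Group data container
#'
#' @param volumes list of spatially normalized `volume3d`s on one grid.
#' @param labels character/factor of group labels ("A"/"B"), one per volume.
#' @param analysis_mask logical array, or `NULL` for the intersection of
#'   the subject masks.
#' @return An object of class `group_data`.
#' @export
group_data <- function(volumes, labels, analysis_mask = NULL) {
  stopifnot(length(volumes) == length(labels), length(volumes) >= 4)
  labels <- as.character(labels)
  stopifnot(length(unique(labels)) == 2)
  if (min(table(labels)) < 2) stop("need at least 2 subjects per group")
  d <- dim(volumes[[1]]$voxels)
  for (v in volumes) {
    stopifnot(inherits(v, "volume3d"), all(dim(v$voxels) == d),
              all(v$spacing == volumes[[1]]$spacing))
  }
  if (is.null(analysis_mask)) {
    analysis_mask <- Reduce(`&`, lapply(volumes, `[[`, "mask"))
  }
  stopifnot(all(dim(analysis_mask) == d))
  if (!any(analysis_mask)) stop("analysis mask is empty")
  structure(list(volumes = volumes, labels = labels,
                 analysis_mask = analysis_mask), class = "group_data")
}

#' Proportional-scaling global normalization
#'
#' Divides each subject volume by its mean in-mask activity and rescales by
#' the grand mean, removing global uptake differences between animals (the
#' standard global-normalization step of voxel-wise metabolic mapping;
#' without it a chance global imbalance between small groups masquerades as
#' brain-wide activation).
#'
#' @param data a [group_data()] object.
#' @return A `group_data` with globally scaled volumes.
#' @export
scale_global <- function(data) {
  stopifnot(inherits(data, "group_data"))
  gm <- vapply(data$volumes, function(v) mean(v$voxels[data$analysis_mask]),
               numeric(1))
  grand <- mean(gm)
  data$volumes <- mapply(function(v, g) {
    v$voxels <- v$voxels * (grand / g)
    v
  }, data$volumes, gm, SIMPLIFY = FALSE)
  data
}

#' Smooth every subject of a group
#'
#' Mask-aware Gaussian smoothing of each subject volume with FWHM equal to
#' `fwhm_factor` times the voxel size per axis (so anisotropic voxels get
#' proportionally anisotropic kernels), to increase signal-to-noise before
#' voxel-wise testing.
#'
#' @param data a [group_data()] object.
#' @param fwhm_factor multiple of the voxel size (default 3; 0 = identity).
#' @return A smoothed `group_data`.
#' @export
smooth_group <- function(data, fwhm_factor = 3) {
  stopifnot(inherits(data, "group_data"), fwhm_factor >= 0)
  if (fwhm_factor == 0) return(data)
  data$volumes <- lapply(data$volumes, function(v) {
    smooth_gaussian(v, fwhm = fwhm_factor * v$spacing)
  })
  data
}

#' Voxel-wise two-sample t-test
#'
#' Pooled-variance Student t at every in-mask voxel with
#' `df = nA + nB - 2`; sign convention: positive t means group B mean above
#' group A mean. One-sided p-values are taken from both tails (`p_pos` for
#' B > A, `p_neg` for B < A). Voxels with zero pooled variance are excluded
#' from all maps and counted as degenerate rather than assigned p = 1, so
#' they do not bias the multiple-testing corrections. Welch's unequal
#' variance form is available via `welch = TRUE`.
#'
#' @param data a [group_data()] object.
#' @param welch use the Welch-Satterthwaite form instead of pooled variance?
#' @return Object of class `stat_maps`: arrays `t_map`, `p_pos`, `p_neg`
#'   (NA outside the analysis mask and at degenerate voxels), scalar `df`
#'   (array for Welch), the `mask` actually analyzed, `n_degenerate`, and
#'   group sizes.
#' @export
voxelwise_ttest <- function(data, welch = FALSE) {
  stopifnot(inherits(data, "group_data"))
  labs <- data$labels
  groups <- sort(unique(labs))
  ia <- labs == groups[1]
  ib <- labs == groups[2]
  na <- sum(ia); nb <- sum(ib)
  if (na < 2 || nb < 2) stop("need at least 2 subjects per group")
  d <- dim(data$volumes[[1]]$voxels)
  mask <- data$analysis_mask
  X <- vapply(data$volumes, function(v) v$voxels[mask],
              numeric(sum(mask)))
  ma <- rowMeans(X[, ia, drop = FALSE])
  mb <- rowMeans(X[, ib, drop = FALSE])
  va <- rowSums((X[, ia, drop = FALSE] - ma)^2) / (na - 1)
  vb <- rowSums((X[, ib, drop = FALSE] - mb)^2) / (nb - 1)
  if (welch) {
    se2 <- va / na + vb / nb
    ok <- se2 > 0
    tval <- (mb - ma) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    s2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    ok <- s2 > 0
    tval <- (mb - ma) / sqrt(s2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  tval[!ok] <- NA
  amask <- mask
  amask[mask] <- ok
  to_map <- function(vals) {
    m <- array(NA_real_, d)
    m[mask] <- vals
    m[!amask] <- NA
    m
  }
  dfv <- if (welch) ifelse(ok, df, NA) else df
  p_pos <- pt(tval, if (welch) dfv else df, lower.tail = FALSE)
  p_neg <- pt(tval, if (welch) dfv else df, lower.tail = TRUE)
  structure(list(t_map = to_map(tval), p_pos = to_map(p_pos),
                 p_neg = to_map(p_neg), df = df, mask = amask,
                 n_degenerate = sum(!ok), n_a = na, n_b = nb,
                 groups = groups),
            class = "stat_maps")
}

#' @export
print.stat_maps <- function(x, ...) {
  cat(sprintf(
    "<stat_maps> %d voxels analyzed (%d degenerate), df = %s, t in [%.2f, %.2f]\n",
    sum(x$mask), x$n_degenerate,
    if (length(x$df) == 1) format(x$df) else "per-voxel",
    min(x$t_map, na.rm = TRUE), max(x$t_map, na.rm = TRUE)))
  invisible(x)
}

#' Benjamini-Hochberg FDR over an in-mask p-map
#'
#' Step-up procedure over the `m` in-mask p-values: with sorted values
#' `p_(1) <= ... <= p_(m)`, the threshold is `p_(k)` for the largest `k`
#' with `p_(k) <= k q / m` (`NA` if no such `k`); `q_map` holds the
#' monotone step-up adjusted p-values.
#'
#' @param p array of p-values.
#' @param mask logical array of voxels to include.
#' @param q target FDR level in (0, 1).
#' @return List `threshold` (p-value cutoff or `NA`), `q_map` (adjusted p,
#'   NA outside mask), `n_discoveries`.
#' @export
fdr_bh <- function(p, mask = NULL, q = 0.05) {
  stopifnot(q > 0, q < 1)
  if (is.null(mask)) mask <- !is.na(p) & array(TRUE, dim(p))
  mask <- mask & !is.na(p)
  pv <- p[mask]
  m <- length(pv)
  stopifnot(m >= 1)
  adj <- stats::p.adjust(pv, method = "BH")
  ps <- sort(pv)
  ok <- ps <= seq_len(m) * q / m
  threshold <- if (any(ok)) ps[max(which(ok))] else NA_real_
  q_map <- array(NA_real_, dim(p))
  q_map[mask] <- adj
  list(threshold = threshold, q_map = q_map,
       n_discoveries = if (is.na(threshold)) 0L else sum(pv <= threshold))
}

#' Family-wise error control
#'
#' `method = "bonferroni"`: `p_fwe = min(1, m p)` over the `m` in-mask
#' voxels. `method = "permutation_maxT"`: group labels are permuted
#' (exhaustively when the number of distinct relabelings is at most
#' `n_perm`, otherwise `n_perm` seeded random draws), the maximum |t| over
#' the mask is recorded per permutation, and
#' `p_fwe(v) = #\{max-T >= |t(v)|\} / P` for exhaustive enumeration or
#' `(1 + #) / (P + 1)` for random sampling. Honest under the spatial
#' dependence smoothing induces.
#'
#' @param maps a [voxelwise_ttest()] result (needed for both methods).
#' @param data the [group_data()] behind `maps` (permutation method only).
#' @param alpha FWE level in (0, 1).
#' @param method `"bonferroni"` or `"permutation_maxT"`.
#' @param n_perm maximum number of permutations.
#' @param seed RNG seed for random permutations.
#' @return List `p_fwe_map`, `threshold` (|t| cutoff for permutation,
#'   p cutoff `alpha / m` for Bonferroni), `method`, `n_perm_used`.
#' @export
fwe_correct <- function(maps, data = NULL, alpha = 0.05,
                        method = c("bonferroni", "permutation_maxT"),
                        n_perm = 1000, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(maps, "stat_maps"), alpha > 0, alpha < 1)
  mask <- maps$mask
  m <- sum(mask)
  if (method == "bonferroni") {
    p2 <- 2 * pmin(maps$p_pos, maps$p_neg)
    p_fwe <- array(NA_real_, dim(p2))
    p_fwe[mask] <- pmin(1, m * p2[mask])
    return(list(p_fwe_map = p_fwe, threshold = alpha / m,
                method = method, n_perm_used = 0L))
  }
  stopifnot(inherits(data, "group_data"))
  labs <- data$labels
  groups <- sort(unique(labs))
  n <- length(labs)
  na <- sum(labs == groups[1])
  all_combs <- choose(n, na)
  if (all_combs < 10) {
    warning("fewer than 10 distinct relabelings; permutation p-values are coarse")
  }
  X <- vapply(data$volumes, function(v) v$voxels[mask], numeric(m))
  tstat <- function(ia) {
    ib <- !ia
    nb <- n - na
    ma <- rowMeans(X[, ia, drop = FALSE])
    mb <- rowMeans(X[, ib, drop = FALSE])
    va <- rowSums((X[, ia, drop = FALSE] - ma)^2) / (na - 1)
    vb <- rowSums((X[, ib, drop = FALSE] - mb)^2) / (nb - 1)
    s2 <- ((na - 1) * va + (nb - 1) * vb) / (n - 2)
    out <- (mb - ma) / sqrt(s2 * (1 / na + 1 / nb))
    out[s2 <= 0] <- 0
    out
  }
  exhaustive <- all_combs <= n_perm
  if (exhaustive) {
    combs <- combn(n, na)
    perms <- lapply(seq_len(ncol(combs)), function(j) {
      ia <- rep(FALSE, n); ia[combs[, j]] <- TRUE; ia
    })
  } else {
    perms <- with_seed(seed, lapply(seq_len(n_perm), function(j) {
      ia <- rep(FALSE, n); ia[sample.int(n, na)] <- TRUE; ia
    }))
  }
  maxT <- vapply(perms, function(ia) max(abs(tstat(ia))), numeric(1))
  P <- length(perms)
  tobs <- abs(maps$t_map[mask])
  cnt <- vapply(tobs, function(t0) sum(maxT >= t0 - 1e-12), numeric(1))
  pv <- if (exhaustive) cnt / P else (1 + cnt) / (P + 1)
  p_fwe <- array(NA_real_, dim(maps$t_map))
  p_fwe[mask] <- pv
  thr <- quantile(maxT, 1 - alpha, type = 1, names = FALSE)
  list(p_fwe_map = p_fwe, threshold = thr, method = method,
       n_perm_used = P)
}

#' Cluster-size filtering of a significance map
#'
#' Labels the 26-connected components of a binary suprathreshold map,
#' removes components smaller than `min_cluster_size` voxels, and tabulates
#' the survivors sorted by size (descending), with peak statistic and peak
#' voxel index when a statistic map is supplied.
#'
#' @param sig_map logical 3D array of suprathreshold voxels.
#' @param min_cluster_size smallest surviving component, voxels (`>= 1`).
#' @param stat_map optional numeric array for peak lookup (|value| maximum).
#' @return List `labels` (integer array, 0 = background, relabeled 1..K by
#'   size rank) and `table` (data frame `label`, `size`, `peak_stat`,
#'   `peak_x`, `peak_y`, `peak_z`, 1-based).
#' @export
cluster_filter <- function(sig_map, min_cluster_size = 1, stat_map = NULL) {
  stopifnot(is.logical(sig_map), length(dim(sig_map)) == 3,
            min_cluster_size >= 1)
  sig_map[is.na(sig_map)] <- FALSE
  lab <- cpp_label_cc(sig_map, dim(sig_map))
  out <- array(0L, dim(sig_map))
  if (max(lab) == 0) {
    return(list(labels = out,
                table = data.frame(label = integer(0), size = integer(0),
                                   peak_stat = numeric(0),
                                   peak_x = integer(0), peak_y = integer(0),
                                   peak_z = integer(0))))
  }
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_cluster_size)
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  rows <- vector("list", length(keep))
  for (r in seq_along(keep)) {
    vox <- which(lab == keep[r])
    out[vox] <- r
    if (!is.null(stat_map)) {
      vals <- stat_map[vox]
      pk <- vox[which.max(abs(vals))]
      pstat <- vals[which.max(abs(vals))]
    } else {
      pk <- vox[1]
      pstat <- NA_real_
    }
    ijk <- arrayInd(pk, dim(sig_map))
    rows[[r]] <- data.frame(label = r, size = sizes[keep[r]],
                            peak_stat = pstat, peak_x = ijk[1],
                            peak_y = ijk[2], peak_z = ijk[3])
  }
  list(labels = out, table = do.call(rbind, rows))
}

#' Full statistics stage
#'
#' Smoothing, t-map, signed p-maps, BH-FDR and FWE maps, and cluster
#' filtering of the FDR-surviving voxels, in one call.
#'
#' @param data a [group_data()] object.
#' @param fwhm_factor smoothing kernel as a multiple of the voxel size.
#' @param q FDR level; `alpha` FWE level.
#' @param fwe_method passed to [fwe_correct()].
#' @param min_cluster_size cluster-extent threshold in voxels.
#' @param global_scaling apply [scale_global()] first? (default `TRUE`).
#' @param welch,n_perm,seed passed through.
#' @return List of class `stats_result`: `maps` (`stat_maps`), `fdr`,
#'   `fwe`, `clusters`, and the parameters used.
#' @export
run_stats <- function(data, fwhm_factor = 3, q = 0.05, alpha = 0.05,
                      fwe_method = "bonferroni", min_cluster_size = 1,
                      welch = FALSE, global_scaling = TRUE, n_perm = 1000,
                      seed = 1L) {
  if (global_scaling) data <- scale_global(data)
  sm <- smooth_group(data, fwhm_factor)
  maps <- voxelwise_ttest(sm, welch = welch)
  p2 <- 2 * pmin(maps$p_pos, maps$p_neg)
  fdr <- fdr_bh(p2, maps$mask, q = q)
  fwe <- fwe_correct(maps, data = sm, alpha = alpha, method = fwe_method,
                     n_perm = n_perm, seed = seed)
  sig <- !is.na(fdr$q_map) & fdr$q_map <= q
  clusters <- cluster_filter(sig, min_cluster_size = min_cluster_size,
                             stat_map = maps$t_map)
  structure(list(maps = maps, fdr = fdr, fwe = fwe, clusters = clusters,
                 params = list(fwhm_factor = fwhm_factor, q = q,
                               alpha = alpha, fwe_method = fwe_method,
                               min_cluster_size = min_cluster_size,
                               welch = welch)),
            class = "stats_result")
}
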