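# Synthetic phantom generator. Produces brain-like activity volumes with
# known internal structure, per-section rigid misalignment, film-style
# 8-bit rendering with dust/overlap artifacts and a standards strip table,
# and two-group studies with a known regional activation — the ground truth
# every downstream stage is validated against.

#' Phantom specification
#'
#' Describes a synthetic brain volume: grid, physical spacing (defaults
#' 10 x 10 um in-plane, 20 um between sections, the acquisition geometry of
#' a cryostat-sectioned mouse brain digitized at 10 um pixels), the baseline
#' activity (nCi/g) of the outer tissue and of nested internal structures,
#' the activity-scale noise, per-section artifact probabilities and the RNG
#' seed. Identical spec + seed reproduce bit-identical phantoms.
#'
#' @param grid_shape integer triple of voxels `(x, y, z)`, each `>= 8`.
#' @param spacing physical voxel size in micrometres.
#' @param structure_levels named numeric vector of baseline activities in
#'   nCi/g; the first entry is the outer tissue shell, later entries are
#'   nested internal structures (placed off-center so that in-plane rotation
#'   is identifiable). Values must be positive and distinct.
#' @param noise_sd Gaussian noise standard deviation on the activity scale.
#' @param artifact_rates named vector with per-section probabilities `dust`
#'   and `overlap`.
#' @param z_profile `"truncated"` (default): the brain outline tapers along
#'   z but still crosses the first and last plane, as when a bregma range
#'   of a larger brain is sectioned; `"closed"`: the outline closes to zero
#'   inside the grid, so the whole brain is contained in the field of view
#'   (used when testing 3D transform recovery, where content cut at the
#'   volume boundary would confound the estimate).
#' @param seed integer RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 40),
                         spacing = c(10, 10, 20),
                         structure_levels = c(cortex = 60, hippocampus = 120,
                                              thalamus = 90),
                         noise_sd = 2,
                         artifact_rates = c(dust = 0.3, overlap = 0.1),
                         z_profile = c("truncated", "closed"),
                         seed = 1L) {
  z_profile <- match.arg(z_profile)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, length(spacing) == 3)
  if (any(grid_shape < 8)) stop("invalid-spec: grid dimensions must be >= 8")
  if (any(spacing <= 0)) stop("invalid-spec: spacings must be positive")
  if (length(structure_levels) < 1 || any(structure_levels <= 0) ||
      anyDuplicated(structure_levels)) {
    stop("invalid-spec: baseline activities must be positive and distinct")
  }
  stopifnot(noise_sd >= 0, all(artifact_rates >= 0), all(artifact_rates <= 1))
  structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                 structure_levels = structure_levels, noise_sd = noise_sd,
                 artifact_rates = artifact_rates, z_profile = z_profile,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Fixed library of internal-structure placements in normalized [-1,1]
# coordinates. Structures are bilateral pairs mirrored about the midline
# (u = 0), as real brain anatomy is: the off-midline placement pins down
# in-plane rotation, while the exact mirror symmetry guarantees that the
# slow section-to-section content change cannot masquerade as a rotation
# (the pair-NCC cost is an even function of the rotation angle for
# midline-symmetric content). `center[1]` is the distance from the midline.
.structure_sites <- list(
  list(center = c(0.30, 0.20, 0), semi = c(0.26, 0.20, 1.25)),
  list(center = c(0.28, -0.26, 0), semi = c(0.22, 0.24, 1.45)),
  list(center = c(0.00, -0.45, 0), semi = c(0.34, 0.14, 1.80)),
  list(center = c(0.00, 0.42, 0), semi = c(0.28, 0.12, 2.00))
)

# Normalized coordinate grids for a phantom spec.
.norm_coords <- function(grid_shape) {
  lapply(grid_shape, function(n) (2 * (0:(n - 1)) - (n - 1)) / (n - 1))
}

#' Generate a phantom activity volume
#'
#' Builds a smooth, brain-shaped activity volume: a tapering, egg-shaped
#' (top/bottom asymmetric) outer region at the first baseline level with
#' nested ellipsoidal structures at the remaining levels, edge-blended with
#' a mask-aware Gaussian so values inside the brain interpolate between the
#' structure baselines, plus optional Gaussian activity noise. Zero outside
#' the brain. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param jitter optional per-subject geometry/intensity jitter, as returned
#'   by the group-study generator: list with `outer_scale`, `center_offsets`
#'   (matrix, one row per internal structure), `axis_scales`, `intensity`.
#' @param effect_mask optional logical array (phantom grid): activity inside
#'   is multiplied by `1 + effect_size` before noise.
#' @param effect_size fractional activity change inside `effect_mask`.
#' @param seed RNG seed override (defaults to `spec$seed`).
#' @return A `volume3d` of activities in nCi/g, with the brain mask.
#' @export
make_phantom_volume <- function(spec, jitter = NULL, effect_mask = NULL,
                                effect_size = 0, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  nc <- .norm_coords(d)
  u <- nc[[1]]; v <- nc[[2]]; w <- nc[[3]]
  os <- if (is.null(jitter)) 1 else jitter$outer_scale
  # z-taper of the outline (coronal extent shrinks toward both poles)
  sz <- if (identical(spec$z_profile, "closed")) {
    sqrt(pmax(0, 1 - (w / 0.85)^2))
  } else {
    sqrt(pmax(0.5, 1 - 0.35 * w^2))
  }
  ax <- 0.68 * os
  ay_top <- 0.48 * os
  ay_bot <- 0.66 * os
  U <- array(rep(u, times = d[2] * d[3]), d)
  V <- array(rep(rep(v, each = d[1]), times = d[3]), d)
  W <- array(rep(w, each = d[1] * d[2]), d)
  S <- array(rep(sz, each = d[1] * d[2]), d)
  ay <- ifelse(V >= 0, ay_top, ay_bot)
  brain <- (U / (ax * S))^2 + (V / (ay * S))^2 <= 1
  lev <- spec$structure_levels
  act <- array(0, d)
  act[brain] <- lev[1]
  if (length(lev) > 1) {
    for (k in 2:length(lev)) {
      site <- .structure_sites[[(k - 2) %% length(.structure_sites) + 1]]
      ctr <- site$center
      semi <- site$semi
      if (!is.null(jitter)) {
        ctr <- ctr + jitter$center_offsets[k - 1, ]
        semi <- semi * jitter$axis_scales[k - 1]
      }
      inside <- ((abs(U) - ctr[1]) / semi[1])^2 +
        ((V - ctr[2]) / semi[2])^2 + ((W - ctr[3]) / semi[3])^2 <= 1
      act[inside & brain] <- lev[k]
    }
  }
  vol <- volume3d(act, spacing = spec$spacing, mask = brain)
  # edge blending: mask-aware smoothing keeps blends between the baselines
  vol <- smooth_gaussian(vol, fwhm = 2.3548 * spec$spacing * c(1, 1, 0.5))
  if (!is.null(effect_mask) && effect_size != 0) {
    stopifnot(all(dim(effect_mask) == d))
    vol$voxels[effect_mask] <- vol$voxels[effect_mask] * (1 + effect_size)
  }
  if (!is.null(jitter) && !is.null(jitter$warp)) {
    # smooth random deformation: local anatomical variability that an
    # affine cannot express (the activation region moves with the anatomy).
    # Edge-replicate padding keeps the boundary planes inside the sampled
    # domain (a few-um displacement must not erase a whole 20-um section).
    vol <- resample_volume(pad_volume_edges(vol, c(2L, 2L, 1L)),
                           bspline = jitter$warp, reference = vol)
  }
  if (!is.null(jitter)) vol$voxels <- vol$voxels * jitter$intensity
  if (spec$noise_sd > 0) {
    noise <- with_seed(seed, rnorm(sum(brain), 0, spec$noise_sd))
    vol$voxels[brain] <- pmax(0, vol$voxels[brain] + noise)
  }
  vol
}

#' Ellipsoidal region mask on a phantom grid
#'
#' @param spec a [phantom_spec()].
#' @param center,semi ellipsoid center and semi-axes in normalized `[-1, 1]`
#'   coordinates. Defaults cover the core of the first internal structure.
#' @return Logical array on the phantom grid.
#' @export
phantom_region_mask <- function(spec, center = c(0.28, 0.18, 0.10),
                                semi = c(0.22, 0.18, 0.40)) {
  d <- spec$grid_shape
  nc <- .norm_coords(d)
  U <- array(rep(nc[[1]], times = d[2] * d[3]), d)
  V <- array(rep(rep(nc[[2]], each = d[1]), times = d[3]), d)
  W <- array(rep(nc[[3]], each = d[1] * d[2]), d)
  ((U - center[1]) / semi[1])^2 + ((V - center[2]) / semi[2])^2 +
    ((W - center[3]) / semi[3])^2 <= 1
}

#' Slice a volume into rigidly perturbed sections
#'
#' Cuts the volume into its z-planes and resamples each under an
#' independently drawn in-plane rigid transform (translations uniform in
#' `+/- max_shift` um, rotation uniform in `+/- max_angle` degrees, about the
#' section center) — the forward model of the mounting misalignment the
#' reconstruction stage must undo. The drawn parameters are recorded in the
#' returned ground truth; with zero bounds the sections equal the volume's
#' planes exactly.
#'
#' @param volume a `volume3d`.
#' @param max_shift,max_angle perturbation bounds (um, degrees), `>= 0`.
#' @param seed integer RNG seed.
#' @return List with `sections` (list of `section_image`) and `truth`
#'   (class `ground_truth`: `per_section_transforms` data frame,
#'   `calibration_pairs` covering the volume's activity range).
#' @export
slice_and_perturb <- function(volume, max_shift = 200, max_angle = 10,
                              seed = 1L) {
  stopifnot(inherits(volume, "volume3d"), max_shift >= 0, max_angle >= 0)
  d <- dim(volume$voxels)
  n <- d[3]
  par <- with_seed(seed, data.frame(
    index = 0:(n - 1),
    tx = runif(n, -max_shift, max_shift),
    ty = runif(n, -max_shift, max_shift),
    theta = runif(n, -max_angle, max_angle)))
  if (max_shift == 0) par$tx <- par$ty <- rep(0, n)
  if (max_angle == 0) par$theta <- rep(0, n)
  sections <- vector("list", n)
  for (k in seq_len(n)) {
    s <- section_image(volume$voxels[, , k], spacing = volume$spacing[1:2],
                       index = k - 1L, mask = volume$mask[, , k])
    tf <- rigid2d(par$tx[k], par$ty[k], par$theta[k],
                  center = section_center(s))
    sections[[k]] <- if (par$tx[k] == 0 && par$ty[k] == 0 &&
                         par$theta[k] == 0) s else resample_section(s, tf)
  }
  truth <- structure(
    list(per_section_transforms = par,
         activation_mask = NULL, effect_size = 0,
         calibration_pairs = default_calibration_pairs(
           1.1 * max(volume$voxels))),
    class = "ground_truth")
  list(sections = sections, truth = truth)
}

#' Default standards for the phantom film model
#'
#' Mildly nonlinear, strictly monotone gray-to-activity pairs covering
#' `[0, a_max]` nCi/g over the full 8-bit range, playing the role of the
#' co-exposed 14C standards strip.
#'
#' @param a_max largest activity the standards must cover (nCi/g).
#' @param n_knots number of standards.
#' @return Data frame with columns `gray`, `nci_per_g`.
#' @export
default_calibration_pairs <- function(a_max, n_knots = 9) {
  gray <- round(seq(0, 255, length.out = n_knots))
  u <- gray / 255
  data.frame(gray = gray, nci_per_g = a_max * (0.7 * u + 0.3 * u^2))
}

#' Render activity sections as 8-bit film scans
#'
#' Maps activities to gray levels through the inverse of the standards'
#' natural-spline calibration curve, quantizes with round-half-up to 0-255
#' (clamping out-of-range activities, as film saturation would), and adds
#' film artifacts: dust speckles (small bright blobs disjoint from tissue)
#' and overlapping-section blobs (a shifted partial copy of the tissue,
#' disjoint from and smaller than the tissue itself).
#'
#' @param sections list of activity-valued `section_image`s.
#' @param truth a `ground_truth` carrying `calibration_pairs`.
#' @param artifact_rates named vector of per-section probabilities `dust`
#'   and `overlap`.
#' @param seed integer RNG seed.
#' @return List with `sections` (8-bit `section_image`s, unmasked),
#'   `standards` (data frame `gray`, `nci_per_g`) and `n_clamped`
#'   (count of activity values outside the calibration range).
#' @export
render_film <- function(sections, truth,
                        artifact_rates = c(dust = 0, overlap = 0),
                        seed = 1L) {
  pairs <- truth$calibration_pairs
  stopifnot(nrow(pairs) >= 4, all(diff(pairs$gray) > 0),
            all(diff(pairs$nci_per_g) > 0))
  act_of_gray <- splinefun(pairs$gray, pairs$nci_per_g, method = "natural")
  gdense <- seq(min(pairs$gray), max(pairs$gray), by = 0.05)
  adense <- act_of_gray(gdense)
  if (any(diff(adense) <= 0)) {
    stop("calibration pairs do not define an invertible activity-gray map")
  }
  gray_of_act <- approxfun(adense, gdense, rule = 2)
  arange <- range(adense)
  n_clamped <- 0L
  dust_rate <- if ("dust" %in% names(artifact_rates))
    artifact_rates[["dust"]] else 0
  overlap_rate <- if ("overlap" %in% names(artifact_rates))
    artifact_rates[["overlap"]] else 0
  out <- with_seed(seed, lapply(sections, function(s) {
    a <- s$pixels
    n_clamped <<- n_clamped + sum(a < arange[1] | a > arange[2])
    a <- pmin(pmax(a, arange[1]), arange[2])
    g <- matrix(floor(gray_of_act(a) + 0.5), nrow(a))
    g <- pmin(pmax(g, 0), 255)
    tissue <- if (is.null(s$mask)) g > otsu_threshold(
      tabulate(as.integer(g) + 1L, 256)) else s$mask
    if (dust_rate > 0 && runif(1) < dust_rate) {
      g <- add_dust(g, tissue)
    }
    if (overlap_rate > 0 && runif(1) < overlap_rate) {
      g <- add_overlap(g, tissue)
    }
    section_image(g, spacing = s$spacing, index = s$index)
  }))
  if (n_clamped > 0) {
    warning(sprintf("%d activity value(s) outside calibration range clamped",
                    n_clamped))
  }
  list(sections = out, standards = pairs, n_clamped = n_clamped)
}

# Paint 1-3 small bright speckles into the background, away from tissue.
add_dust <- function(g, tissue) {
  d <- dim(g)
  far <- !(EBImage::dilate(matrix(as.numeric(tissue), d[1]),
                           EBImage::makeBrush(9, "disc")) > 0.5)
  far[c(1:3, (d[1] - 2):d[1]), ] <- FALSE
  far[, c(1:3, (d[2] - 2):d[2])] <- FALSE
  spots <- which(far)
  if (!length(spots)) return(g)
  for (s in seq_len(sample(3, 1))) {
    ctr <- arrayInd(sample(spots, 1), d)
    r <- sample(1:2, 1)
    ii <- pmax(1, ctr[1] - r):pmin(d[1], ctr[1] + r)
    jj <- pmax(1, ctr[2] - r):pmin(d[2], ctr[2] + r)
    disk <- outer(ii - ctr[1], jj - ctr[2], function(a, b) a^2 + b^2 <= r^2)
    blk <- g[ii, jj, drop = FALSE]
    blk[disk] <- sample(230:255, 1)
    g[ii, jj] <- blk
  }
  g
}

# Paste a shifted partial copy of the tissue into free background: emulates
# a neighbouring section overlapping the frame. Kept disjoint from and
# smaller than the tissue so the cleaning stage can remove it.
add_overlap <- function(g, tissue) {
  d <- dim(g)
  idx <- which(tissue, arr.ind = TRUE)
  if (nrow(idx) < 20) return(g)
  # half of the tissue (rows up to the median x), shifted
  half <- idx[idx[, 1] <= stats::median(idx[, 1]), , drop = FALSE]
  wbb <- diff(range(idx[, 1])) + 1
  shift <- c(round(1.25 * wbb) * sample(c(-1, 1), 1), sample(-3:3, 1))
  ni <- half[, 1] + shift[1]
  nj <- half[, 2] + shift[2]
  ok <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2]
  if (!any(ok)) return(g)
  far <- !(EBImage::dilate(matrix(as.numeric(tissue), d[1]),
                           EBImage::makeBrush(7, "disc")) > 0.5)
  keep <- ok
  keep[ok] <- far[cbind(ni[ok], nj[ok])]
  if (sum(keep) < 10) return(g)
  g[cbind(ni[keep], nj[keep])] <- g[half[keep, , drop = FALSE]]
  g
}

#' Generate a two-group phantom study
#'
#' Draws `2 * n_per_group` subjects as per-subject jittered phantoms
#' (geometry and global-intensity variability), applies a regional
#' activation to group B (activity multiplied by `1 + effect_size` inside
#' `effect_region`), and — unless `render = FALSE` — slices each subject
#' into perturbed sections and renders them as artifacted 8-bit film scans
#' with a standards table. The ground-truth activation mask travels with
#' the bundle. With `effect_size = 0` the two groups are exchangeable draws
#' from one distribution (null calibration studies).
#'
#' @param spec a [phantom_spec()].
#' @param n_per_group subjects per group, `>= 2`.
#' @param effect_region logical array on the phantom grid, or `NULL` for
#'   the default region from [phantom_region_mask()].
#' @param effect_size fractional activity increase in group B.
#' @param seed study-level RNG seed.
#' @param max_shift,max_angle per-section perturbation bounds (um, degrees).
#' @param warp_sd standard deviation (um) of the random smooth per-subject
#'   deformation (control-point displacements of a coarse B-spline field)
#'   modelling local anatomical variability; 0 disables it.
#' @param render if `FALSE`, skip slicing and film rendering and return
#'   ground-truth volumes only (used for statistics-stage studies where the
#'   subjects share the phantom grid).
#' @return List of class `phantom_study`: `subjects` (each with `id`,
#'   `group`, `volume`, and if rendered `sections`, `film`, `truth`),
#'   `activation_mask`, `effect_size`, `spec`, `n_per_group`.
#' @export
make_group_study <- function(spec, n_per_group, effect_region = NULL,
                             effect_size = 0, seed = spec$seed,
                             max_shift = 200, max_angle = 10,
                             warp_sd = 5, render = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"), n_per_group >= 2)
  if (is.null(effect_region)) effect_region <- phantom_region_mask(spec)
  stopifnot(all(dim(effect_region) == spec$grid_shape))
  n_sub <- 2L * n_per_group
  n_struct <- max(1L, length(spec$structure_levels) - 1L)
  ref <- volume3d(array(0, spec$grid_shape), spacing = spec$spacing)
  wgrid <- bspline_grid(ref, (spec$grid_shape - 1) * spec$spacing / 3)
  draws <- with_seed(seed, list(
    sub_seeds = matrix(sample.int(.Machine$integer.max - 1, n_sub * 3),
                       n_sub, 3),
    jitters = lapply(seq_len(n_sub), function(i) list(
      outer_scale = rnorm(1, 1, 0.02),
      center_offsets = matrix(rnorm(n_struct * 3, 0, 0.02), n_struct, 3),
      axis_scales = rnorm(n_struct, 1, 0.02),
      intensity = rnorm(1, 1, 0.03),
      warp = if (warp_sd > 0) {
        w <- wgrid
        w$coef <- array(rnorm(prod(w$shape) * 3, 0, warp_sd), c(w$shape, 3))
        w
      }))))
  subjects <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    grp <- if (i <= n_per_group) "A" else "B"
    es <- if (grp == "B") effect_size else 0
    vol <- make_phantom_volume(spec, jitter = draws$jitters[[i]],
                               effect_mask = effect_region, effect_size = es,
                               seed = draws$sub_seeds[i, 1])
    subj <- list(id = sprintf("subj%02d", i), group = grp, volume = vol)
    if (render) {
      sl <- slice_and_perturb(vol, max_shift = max_shift,
                              max_angle = max_angle,
                              seed = draws$sub_seeds[i, 2])
      film <- render_film(sl$sections, sl$truth,
                          artifact_rates = spec$artifact_rates,
                          seed = draws$sub_seeds[i, 3])
      subj$sections <- sl$sections
      subj$truth <- sl$truth
      subj$film <- film
    }
    subjects[[i]] <- subj
  }
  structure(list(subjects = subjects, activation_mask = effect_region,
                 effect_size = effect_size, spec = spec,
                 n_per_group = as.integer(n_per_group)),
            class = "phantom_study")
}
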