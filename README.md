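# autorad3d

3D reconstruction and voxel-wise statistical analysis of quantitative
2-deoxyglucose (2DG) autoradiographs of serially sectioned mouse brain.

High-resolution ^14^C autoradiography measures cerebral glucose
metabolism at film resolution, but destroys the brain's 3D consistency:
each animal ends up as ~150 independent 20-µm coronal sections digitized
as 8-bit TIFFs. `autorad3d` rebuilds and compares those brains without
region-of-interest hypotheses:

1. **Clean** each section — Otsu threshold, binary opening, largest
   8-connected component — removing dust and overlapping-section
   artifacts.
2. **Calibrate** gray levels to radioactivity (nCi/g) with a natural
   cubic spline through the co-exposed ^14^C standards.
3. **Reconstruct** each brain by stacking sections and sequentially
   realigning them from the center outward, each section rigidly
   registered to its aligned neighbour by maximizing normalized
   cross-correlation (×4-downsampled first, refined at full resolution).
4. **Normalize** every brain to a smoothed reference subject
   (FWHM = 3 × voxel) with a 12-DOF affine followed by a cubic B-spline
   free-form deformation, multi-resolution, NCC metric.
5. **Test** voxel-wise with a pooled two-sample t: signed one-sided
   p-maps, Benjamini–Hochberg FDR, family-wise error control (Bonferroni
   or permutation max-T), and 26-connected cluster-size filtering.

At a voxel with group means \(\bar{x}_A, \bar{x}_B\) and pooled variance
\(s^2\), the map holds
\(t = (\bar{x}_B - \bar{x}_A) / \sqrt{s^2 (1/n_A + 1/n_B)}\) with
\(df = n_A + n_B - 2\); discoveries are the voxels whose BH-adjusted
two-sided p falls below the chosen q, filtered by cluster extent.

A built-in phantom generator produces synthetic studies — brain-shaped
activity volumes with internal structures, per-section rigid
misalignment, film-style 8-bit rendering with a standards table and
artifacts, and two-group designs with a known activation region — so the
whole chain is testable against ground truth without film data.

## Worked example

```r
library(autorad3d)

# a synthetic two-group study: 8 vs 8 subjects, 15% activation in group B
spec  <- phantom_spec(seed = 1)                       # 64 x 64 x 40 voxels
study <- make_group_study(spec, n_per_group = 8, effect_size = 0.15,
                          seed = 1, render = FALSE)   # volumes + ground truth

gd  <- group_data(lapply(study$subjects, `[[`, "volume"),
                  vapply(study$subjects, `[[`, "", "group"))
res <- run_stats(gd, min_cluster_size = 5)            # smooth, t, FDR, FWE
res$maps
#> <stat_maps> 39088 voxels analyzed (0 degenerate), df = 14, t in [-5.33, 36.22]
res$clusters$table
#>   label size peak_stat peak_x peak_y peak_z
#> 1     1 1055 36.219931     38     38     21
#> 2     2   12 -5.325617     34     17      7
```

The cluster table lists the FDR-surviving (q = 0.05) 26-connected
clusters sorted by size. The dominant cluster (1055 voxels, peak
t = 36.2 at voxel (38, 38, 21)) sits on the region where the generator
injected the 15% activation — its Dice overlap with the ground-truth
mask is 0.86; the 12-voxel negative cluster is a boundary artifact of
the per-subject anatomy jitter.

The same analysis runs file-to-file. `write_phantom_study()` lays a
study out as per-subject film TIFFs, standards CSVs and a YAML config,
and `run_pipeline()` executes the five steps, persisting every
intermediate (cleaned TIFFs, calibrated/reconstructed/normalized NIfTI
volumes, statistical maps) under the configured output directory:

```r
dir <- tempfile("study")
write_phantom_study(make_group_study(phantom_spec(grid_shape = c(48, 48, 12),
                                                  seed = 5),
                                     n_per_group = 2, effect_size = 0.15,
                                     seed = 5, max_shift = 60, max_angle = 4),
                    dir, seed = 5)
config <- read_study_config(file.path(dir, "study.yaml"))
run_pipeline(config)
#> step clean: running
#> step calibrate: running
#> step reconstruct: running
#> step normalize: running
#> step stats: running
list.files(file.path(dir, "derived", "stats"))
#> [1] "clusters.csv"   "clusters.nii.gz" "p_fwe.nii.gz"   "p_neg.nii.gz"
#> [5] "p_pos.nii.gz"   "q_fdr.nii.gz"    "tmap.nii.gz"
```

Re-running `run_pipeline(config)` is a no-op: a JSON manifest tracks
per-step parameter hashes and output checksums. (At this demonstration
size — 2 + 2 subjects, df = 2 — no cluster survives FDR; the maps are
still written.)

A command-line driver wraps the same functions:

```sh
Rscript inst/cli/autorad3d.R phantom --out study_dir --seed 1 --subjects 4
Rscript inst/cli/autorad3d.R run --config study_dir/study.yaml
```

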