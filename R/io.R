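# File I/O for the formats the pipeline touches (8-bit grayscale TIFF
# sections, standards CSV, NIfTI-1 / MetaImage volumes, YAML study
# configuration, JSON ground truth) and the five-step pipeline driver.

#' Read a directory of section TIFFs
#'
#' Sections are single-page 8-bit grayscale TIFFs named `<subject>_s###.tif`
#' and ordered by the embedded index, which must be contiguous from 0.
#' Pixel spacing comes from the caller (section order and spacing are study
#' metadata, not TIFF payload); if TIFF resolution tags are present and
#' disagree, the configured spacing wins with a warning.
#'
#' @param dir directory containing the TIFFs.
#' @param spacing in-plane pixel spacing `(dx, dy)` in micrometres.
#' @return List of `section_image`s sorted by index.
#' @export
read_sections <- function(dir, spacing = c(10, 10)) {
  files <- list.files(dir, pattern = "_s[0-9]+\\.tif$", full.names = TRUE)
  if (!length(files)) stop("no section TIFFs (*_s###.tif) in ", dir)
  idx <- as.integer(sub(".*_s([0-9]+)\\.tif$", "\\1", files))
  if (anyDuplicated(idx)) {
    stop("duplicate section indices: ",
         paste(idx[duplicated(idx)], collapse = ", "))
  }
  o <- order(idx)
  files <- files[o]; idx <- idx[o]
  expected <- seq(0L, max(idx))
  miss <- setdiff(expected, idx)
  if (idx[1] != 0L || length(miss)) {
    stop("section index gap: missing ",
         paste(if (idx[1] != 0L) union(0L, miss) else miss, collapse = ", "))
  }
  lapply(seq_along(files), function(i) {
    m <- tiff::readTIFF(files[i], as.is = TRUE, info = TRUE)
    if (length(dim(m)) != 2) {
      stop("not 8-bit grayscale (multi-channel): ", files[i])
    }
    bits <- attr(m, "bits.per.sample")
    if ((!is.null(bits) && bits != 8) || max(m) > 255 || min(m) < 0) {
      stop("not 8-bit: ", files[i])
    }
    xr <- attr(m, "x.resolution")
    if (!is.null(xr) && is.finite(xr) && xr > 0) {
      # TIFF resolution is px per unit (cm when unit tag = 3): compare
      tag_dx <- 1e4 / xr
      if (abs(tag_dx - spacing[1]) > 0.01 * spacing[1]) {
        warning("TIFF resolution tag disagrees with configured spacing; ",
                "using configured spacing")
      }
    }
    px <- t(m)
    attributes(px) <- list(dim = dim(px))
    section_image(px, spacing = spacing, index = idx[i])
  })
}

#' Write sections as 8-bit grayscale TIFFs
#'
#' @param sections list of `section_image`s with integer gray pixels 0-255.
#' @param dir output directory (created if needed).
#' @param subject subject id used in the `<subject>_s###.tif` names.
#' @return Invisibly, the written paths.
#' @export
write_sections <- function(sections, dir, subject) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(sections, function(s) {
    p <- file.path(dir, sprintf("%s_s%03d.tif", subject, s$index))
    tiff::writeTIFF(t(pmin(pmax(round(s$pixels), 0), 255)) / 255, p,
                    bits.per.sample = 8L)
    p
  }, character(1))
  invisible(paths)
}

#' Read / write a standards table
#'
#' CSV with header `gray,nci_per_g`, one co-exposed standard per row.
#'
#' @param path CSV path.
#' @return `read_standards`: data frame with columns `gray`, `nci_per_g`.
#' @export
read_standards <- function(path) {
  s <- read.csv(path)
  stopifnot(all(c("gray", "nci_per_g") %in% names(s)))
  s[, c("gray", "nci_per_g")]
}

#' @rdname read_standards
#' @param standards data frame with columns `gray`, `nci_per_g`.
#' @export
write_standards <- function(standards, path) {
  write.csv(standards[, c("gray", "nci_per_g")], path, row.names = FALSE)
  invisible(path)
}

#' Write / read a volume (NIfTI-1 or MetaImage)
#'
#' Format follows the file extension: `.nii` / `.nii.gz` (NIfTI-1, spacing
#' converted um -> mm per that format's convention) or `.mha` (MetaImage,
#' spacing kept in the native unit). Voxels round-trip bit-exactly (doubles)
#' and spacing within 1e-6.
#'
#' @param volume a `volume3d`.
#' @param path output path.
#' @return `write_volume` returns the path invisibly; `read_volume` a
#'   `volume3d` (mask all-true; masks are stored as companion volumes).
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume3d"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(volume$voxels)
    RNifti::pixdim(img) <- volume$spacing / 1000
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.mha$", path)) {
    write_metaimage(volume, path)
  } else {
    stop("unsupported volume format: ", path)
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    vox <- array(as.numeric(img), dim(img))
    volume3d(vox, spacing = RNifti::pixdim(img)[1:3] * 1000)
  } else if (grepl("\\.mha$", path)) {
    read_metaimage(path)
  } else {
    stop("unsupported volume format: ", path)
  }
}

# Minimal MetaImage (.mha) writer/reader: uncompressed local raw,
# MET_DOUBLE, little-endian — enough for ITK-ecosystem interchange.
write_metaimage <- function(volume, path) {
  d <- dim(volume$voxels)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           sprintf("Offset = %g %g %g", volume$origin[1], volume$origin[2],
                   volume$origin[3]),
           sprintf("ElementSpacing = %g %g %g", volume$spacing[1],
                   volume$spacing[2], volume$spacing[3]),
           sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
           "ElementType = MET_DOUBLE", "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.numeric(volume$voxels), con, size = 8, endian = "little")
  invisible(path)
}

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    hdr <- c(hdr, line)
    if (grepl("^ElementDataFile", line)) break
  }
  get_field <- function(key) {
    l <- grep(paste0("^", key, " ="), hdr, value = TRUE)
    strsplit(sub(".*= *", "", l[1]), " +")[[1]]
  }
  d <- as.integer(get_field("DimSize"))
  sp <- as.numeric(get_field("ElementSpacing"))
  off <- as.numeric(get_field("Offset"))
  stopifnot(get_field("ElementType") == "MET_DOUBLE")
  vox <- readBin(con, numeric(), n = prod(d), size = 8, endian = "little")
  volume3d(array(vox, d), spacing = sp, origin = off)
}

write_mask_volume <- function(mask, spacing, path) {
  write_volume(volume3d(array(as.numeric(mask), dim(mask)),
                        spacing = spacing), path)
}

read_mask_volume <- function(path) {
  v <- read_volume(path)
  v$voxels > 0.5
}

#' Write a phantom study to disk
#'
#' Lays a [make_group_study()] bundle out as the raw inputs the pipeline
#' expects: per-subject film TIFFs and standards CSV, a ground-truth JSON,
#' and a ready-to-run study YAML.
#'
#' @param study a rendered `phantom_study`.
#' @param dir output directory.
#' @param seed seed recorded in the study config.
#' @return Invisibly, the path to the written `study.yaml`.
#' @export
write_phantom_study <- function(study, dir, seed = 1L) {
  stopifnot(inherits(study, "phantom_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- lapply(study$subjects, function(s) {
    if (is.null(s$film)) stop("study was generated with render = FALSE")
    sdir <- file.path(dir, s$id)
    write_sections(s$film$sections, file.path(sdir, "sections"), s$id)
    write_standards(s$film$standards, file.path(sdir, "standards.csv"))
    jsonlite::write_json(
      list(per_section_transforms = s$truth$per_section_transforms,
           effect_size = study$effect_size),
      file.path(sdir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
    list(id = s$id, sections_dir = file.path(s$id, "sections"),
         standards_csv = file.path(s$id, "standards.csv"), group = s$group)
  })
  cfg <- list(
    schema_version = 1,
    subjects = subjects,
    template_subject = study$subjects[[1]]$id,
    spacing = as.numeric(study$spec$spacing[1:2]),
    dz = as.numeric(study$spec$spacing[3]),
    seed = as.integer(seed),
    output_dir = "derived",
    cleaning = list(opening_radius = 30, min_component_pixels = 20,
                    tissue_bright = TRUE),
    calibration = list(method = "spline", out_of_range = "clamp"),
    reconstruction = list(downsample = 4, refine_full = TRUE),
    normalization = list(fwhm_factor = 3, grid_levels = 1,
                         maxit_bspline = 30),
    stats = list(fwhm_factor = 3, q = 0.05, alpha = 0.05,
                 fwe_method = "bonferroni", min_cluster_size = 5))
  yaml::write_yaml(cfg, file.path(dir, "study.yaml"))
  invisible(file.path(dir, "study.yaml"))
}

.config_keys <- c("schema_version", "subjects", "template_subject",
                  "spacing", "dz", "seed", "output_dir", "cleaning",
                  "calibration", "reconstruction", "normalization", "stats")

#' Load and validate a study configuration
#'
#' YAML with a versioned schema: subject table (id, section directory,
#' standards CSV, group label), template subject, physical spacing, per-step
#' parameters, seed and output directory. Unknown keys are rejected and
#' every referenced path must exist; relative paths resolve against the
#' YAML's directory.
#'
#' @param path path to the study YAML.
#' @return An object of class `study_config`.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  need <- c("subjects", "template_subject", "spacing", "dz", "output_dir")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("missing config key(s): ", paste(miss, collapse = ", "))
  ids <- vapply(cfg$subjects, `[[`, "", "id")
  if (!(cfg$template_subject %in% ids)) {
    stop("template_subject not among subjects")
  }
  for (s in cfg$subjects) {
    sd <- file.path(base, s$sections_dir)
    sc <- file.path(base, s$standards_csv)
    if (!dir.exists(sd)) stop("missing sections dir: ", sd)
    if (!file.exists(sc)) stop("missing standards CSV: ", sc)
  }
  cfg$base_dir <- base
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "study_config")
}

# md5 of an arbitrary R object, via a canonical serialization.
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

file_hashes <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

.pipeline_steps <- c("clean", "calibrate", "reconstruct", "normalize",
                     "stats")

#' Run the five-step pipeline
#'
#' Executes the requested steps in the fixed order clean -> calibrate ->
#' reconstruct -> normalize -> stats, persisting every intermediate as a
#' standard-format file (TIFF, NIfTI, CSV) under the configured output
#' directory. A JSON manifest records per-step status, a parameter hash and
#' output checksums; re-running a completed step with unchanged inputs and
#' parameters is a no-op. Running a step whose prerequisite has not been
#' completed raises a dependency error naming the missing step.
#'
#' @param config a [read_study_config()] object.
#' @param steps subset of `c("clean", "calibrate", "reconstruct",
#'   "normalize", "stats")`.
#' @param quiet suppress progress messages?
#' @return The updated manifest (invisibly a list), written alongside the
#'   outputs as `manifest.json`.
#' @export
run_pipeline <- function(config, steps = .pipeline_steps, quiet = FALSE) {
  stopifnot(inherits(config, "study_config"))
  steps <- match.arg(steps, .pipeline_steps, several.ok = TRUE)
  steps <- .pipeline_steps[.pipeline_steps %in% steps]
  out_root <- file.path(config$base_dir, config$output_dir)
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  man_path <- file.path(out_root, "manifest.json")
  manifest <- if (file.exists(man_path)) {
    jsonlite::read_json(man_path, simplifyVector = FALSE)
  } else {
    list(tool = "autorad3d", version = as.character(
      utils::packageVersion("autorad3d")), steps = list())
  }
  say <- function(...) if (!quiet) message(...)
  ids <- vapply(config$subjects, `[[`, "", "id")
  step_done <- function(step) {
    st <- manifest$steps[[step]]
    !is.null(st) && identical(st$status, "completed") &&
      all(file.exists(file.path(out_root, names(st$outputs))))
  }
  check_dep <- function(step) {
    pos <- match(step, .pipeline_steps)
    if (pos > 1) {
      prev <- .pipeline_steps[pos - 1]
      if (!step_done(prev)) {
        stop(sprintf("dependency error: step '%s' requires completed step '%s'",
                     step, prev))
      }
    }
  }
  record <- function(step, hash, outputs) {
    rel <- sub(paste0("^", out_root, "/?"), "", outputs)
    manifest$steps[[step]] <<- list(
      status = "completed", param_hash = hash,
      outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                                rel),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  up_to_date <- function(step, hash) {
    st <- manifest$steps[[step]]
    ok <- !is.null(st) && identical(st$status, "completed") &&
      identical(st$param_hash, hash) &&
      all(file.exists(file.path(out_root, names(st$outputs))))
    if (ok) {
      cur <- as.character(tools::md5sum(file.path(out_root,
                                                  names(st$outputs))))
      ok <- identical(cur, as.character(unlist(st$outputs)))
    }
    ok
  }

  for (step in steps) {
    check_dep(step)
    hash <- step_hash(config, step, out_root)
    if (up_to_date(step, hash)) {
      say("step ", step, ": up to date, skipped")
      next
    }
    say("step ", step, ": running")
    outputs <- switch(step,
      clean = step_clean(config, out_root),
      calibrate = step_calibrate(config, out_root),
      reconstruct = step_reconstruct(config, out_root),
      normalize = step_normalize(config, out_root),
      stats = step_stats(config, out_root))
    record(step, hash, outputs)
  }
  invisible(manifest)
}

# Hash covering the step's parameters and its raw inputs.
step_hash <- function(config, step, out_root) {
  pars <- switch(step,
    clean = list(config$cleaning, config$spacing),
    calibrate = list(config$calibration, config$dz),
    reconstruct = config$reconstruction,
    normalize = list(config$normalization, config$template_subject),
    stats = list(config$stats, lapply(config$subjects, `[[`, "group"),
                 config$seed))
  inputs <- if (step == "clean") {
    unlist(lapply(config$subjects, function(s) {
      list.files(file.path(config$base_dir, s$sections_dir),
                 full.names = TRUE)
    }))
  } else if (step == "calibrate") {
    vapply(config$subjects, function(s) {
      file.path(config$base_dir, s$standards_csv)
    }, character(1))
  } else {
    character(0)
  }
  object_hash(list(pars, file_hashes(inputs)))
}

step_clean <- function(config, out_root) {
  pars <- config$cleaning
  cp <- cleaning_params(opening_radius = pars$opening_radius,
                        min_component_pixels = pars$min_component_pixels,
                        tissue_bright = pars$tissue_bright)
  unlist(lapply(config$subjects, function(s) {
    secs <- read_sections(file.path(config$base_dir, s$sections_dir),
                          spacing = config$spacing)
    cleaned <- tryCatch(clean_subject(secs, cp), error = function(e) {
      stop(sprintf("subject %s: %s", s$id, conditionMessage(e)))
    })
    p1 <- write_sections(cleaned, file.path(out_root, s$id, "clean"), s$id)
    mdir <- file.path(out_root, s$id, "clean_mask")
    dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
    p2 <- vapply(cleaned, function(cs) {
      p <- file.path(mdir, sprintf("%s_s%03d.tif", s$id, cs$index))
      tiff::writeTIFF(t(cs$mask * 1), p, bits.per.sample = 8L)
      p
    }, character(1))
    c(p1, p2)
  }))
}

step_calibrate <- function(config, out_root) {
  unlist(lapply(config$subjects, function(s) {
    cdir <- file.path(out_root, s$id, "clean")
    secs <- read_sections(cdir, spacing = config$spacing)
    secs <- lapply(secs, function(cs) {
      mp <- file.path(out_root, s$id, "clean_mask",
                      sprintf("%s_s%03d.tif", s$id, cs$index))
      cs$mask <- t(tiff::readTIFF(mp)) > 0.5
      cs
    })
    curve <- fit_calibration(
      read_standards(file.path(config$base_dir, s$standards_csv)),
      method = config$calibration$method)
    cal <- lapply(secs, apply_calibration, curve = curve,
                  out_of_range = config$calibration$out_of_range)
    vol <- stack_sections(cal, dz = config$dz)
    p1 <- file.path(out_root, s$id, "calibrated.nii.gz")
    p2 <- file.path(out_root, s$id, "calibrated_mask.nii.gz")
    write_volume(vol, p1)
    write_mask_volume(vol$mask, vol$spacing, p2)
    c(p1, p2)
  }))
}

step_reconstruct <- function(config, out_root) {
  unlist(lapply(config$subjects, function(s) {
    vol <- read_volume(file.path(out_root, s$id, "calibrated.nii.gz"))
    vol$mask <- read_mask_volume(file.path(out_root, s$id,
                                           "calibrated_mask.nii.gz"))
    r <- align_stack_center_out(vol,
                                downsample = config$reconstruction$downsample,
                                refine_full =
                                  config$reconstruction$refine_full)
    p1 <- file.path(out_root, s$id, "reconstructed.nii.gz")
    p2 <- file.path(out_root, s$id, "reconstructed_mask.nii.gz")
    p3 <- file.path(out_root, s$id, "alignment_report.json")
    write_volume(r$volume, p1)
    write_mask_volume(r$volume$mask, r$volume$spacing, p2)
    jsonlite::write_json(r$report$pairs, p3, digits = NA)
    c(p1, p2, p3)
  }))
}

step_normalize <- function(config, out_root) {
  tid <- config$template_subject
  tvol <- read_volume(file.path(out_root, tid, "reconstructed.nii.gz"))
  tvol$mask <- read_mask_volume(file.path(out_root, tid,
                                          "reconstructed_mask.nii.gz"))
  template <- prepare_template(tvol, config$normalization$fwhm_factor)
  unlist(lapply(config$subjects, function(s) {
    p1 <- file.path(out_root, s$id, "normalized.nii.gz")
    p2 <- file.path(out_root, s$id, "normalized_mask.nii.gz")
    if (s$id == tid) {
      # template subject already defines the reference space
      write_volume(tvol, p1)
      write_mask_volume(tvol$mask, tvol$spacing, p2)
      return(c(p1, p2))
    }
    vol <- read_volume(file.path(out_root, s$id, "reconstructed.nii.gz"))
    vol$mask <- read_mask_volume(file.path(out_root, s$id,
                                           "reconstructed_mask.nii.gz"))
    nr <- normalize_to_template(
      vol, template, grid_levels = config$normalization$grid_levels,
      maxit_bspline = config$normalization$maxit_bspline)
    write_volume(nr$warped, p1)
    write_mask_volume(nr$warped$mask, nr$warped$spacing, p2)
    c(p1, p2)
  }))
}

step_stats <- function(config, out_root) {
  vols <- lapply(config$subjects, function(s) {
    v <- read_volume(file.path(out_root, s$id, "normalized.nii.gz"))
    v$mask <- read_mask_volume(file.path(out_root, s$id,
                                         "normalized_mask.nii.gz"))
    v
  })
  labels <- vapply(config$subjects, `[[`, "", "group")
  gd <- group_data(vols, labels)
  sp <- config$stats
  res <- run_stats(gd, fwhm_factor = sp$fwhm_factor, q = sp$q,
                   alpha = sp$alpha, fwe_method = sp$fwe_method,
                   min_cluster_size = sp$min_cluster_size,
                   seed = config$seed)
  sdir <- file.path(out_root, "stats")
  dir.create(sdir, showWarnings = FALSE)
  spacing <- vols[[1]]$spacing
  wv <- function(arr, name) {
    a <- arr
    a[is.na(a)] <- 0
    p <- file.path(sdir, name)
    write_volume(volume3d(array(a, dim(arr)), spacing = spacing), p)
    p
  }
  paths <- c(wv(res$maps$t_map, "tmap.nii.gz"),
             wv(res$maps$p_pos, "p_pos.nii.gz"),
             wv(res$maps$p_neg, "p_neg.nii.gz"),
             wv(res$fwe$p_fwe_map, "p_fwe.nii.gz"),
             wv(res$fdr$q_map, "q_fdr.nii.gz"),
             wv(res$clusters$labels, "clusters.nii.gz"))
  cp <- file.path(sdir, "clusters.csv")
  write.csv(res$clusters$table, cp, row.names = FALSE)
  c(paths, cp)
}
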