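# Section cleaning: Otsu thresholding, morphological opening, largest
# connected component. Separates brain tissue from film background, dust
# and overlapping-section artifacts before calibration and stacking.

#' Otsu threshold of a 256-bin histogram
#'
#' Returns the integer threshold `t` maximizing the between-class variance
#' `sigma2_B(t) = w0(t) w1(t) (mu0(t) - mu1(t))^2`, where class 0 holds gray
#' levels `<= t` and class 1 the rest. All 255 candidate thresholds are
#' scored (via cumulative sums); ties are broken toward the lowest `t` so
#' the result is deterministic.
#'
#' @param histogram integer vector of 256 bin counts for gray levels 0--255.
#' @return Integer threshold in `0..254`.
#' @export
otsu_threshold <- function(histogram) {
  stopifnot(length(histogram) == 256, all(histogram >= 0))
  if (sum(histogram > 0) < 2) {
    stop("degenerate-histogram: fewer than 2 nonzero bins")
  }
  g <- 0:255
  n <- sum(histogram)
  w0 <- cumsum(histogram) / n
  s0 <- cumsum(histogram * g) / n
  mu_t <- s0[256]
  w1 <- 1 - w0
  # candidates t = 0..254; sigma2_B = (mu_t*w0 - s0)^2 / (w0*w1)
  num <- (mu_t * w0 - s0)[1:255]^2
  den <- (w0 * w1)[1:255]
  s2 <- ifelse(den > 0, num / den, -Inf)
  which.max(s2) - 1L
}

#' Cleaning parameters
#'
#' @param opening_radius radius of the disk structuring element for binary
#'   opening, in micrometres (default 50, i.e. 5 px at 10 um pixels).
#' @param min_component_pixels smallest acceptable tissue component size.
#' @param tissue_bright `TRUE` if tissue gray levels are above background
#'   (digitized uptake bright), `FALSE` for the opposite polarity.
#' @return An object of class `cleaning_params`.
#' @export
cleaning_params <- function(opening_radius = 50, min_component_pixels = 1L,
                            tissue_bright = TRUE) {
  stopifnot(opening_radius >= 0, min_component_pixels >= 1)
  structure(list(opening_radius = opening_radius,
                 min_component_pixels = as.integer(min_component_pixels),
                 tissue_bright = isTRUE(tissue_bright)),
            class = "cleaning_params")
}

#' Clean one digitized section
#'
#' Pipeline: Otsu threshold of the 8-bit histogram (polarity-aware), binary
#' opening with a disk, selection of the single largest 8-connected
#' foreground component, then masking (pixels outside the mask set to 0).
#' Removes dust speckles and disjoint overlapping-section fragments.
#'
#' @param section a `section_image` with 8-bit gray pixels.
#' @param params a [cleaning_params()] object.
#' @return The section with `mask` set and background zeroed.
#' @export
clean_section <- function(section, params = cleaning_params()) {
  stopifnot(inherits(section, "section_image"))
  px <- section$pixels
  h <- tabulate(as.integer(px) + 1L, nbins = 256)
  t <- otsu_threshold(h)
  fg <- if (params$tissue_bright) px > t else px < t
  r_px <- round(params$opening_radius / section$spacing[1])
  if (r_px >= 1) {
    brush <- EBImage::makeBrush(2L * as.integer(r_px) + 1L, shape = "disc")
    fg <- EBImage::opening(matrix(as.numeric(fg), nrow(px)), brush) > 0.5
  }
  if (!any(fg)) {
    stop(sprintf("empty-mask: section %d has no foreground after opening",
                 section$index))
  }
  lab <- cpp_label_cc(fg, c(dim(fg), 1L))
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  if (sizes[keep] < params$min_component_pixels) {
    stop(sprintf("empty-mask: section %d largest component below %d pixels",
                 section$index, params$min_component_pixels))
  }
  mask <- matrix(lab == keep, nrow(px))
  px[!mask] <- 0
  section_image(px, spacing = section$spacing, index = section$index,
                mask = mask)
}

#' Clean every section of a subject
#'
#' Applies [clean_section()] to an ordered list of sections, preserving
#' order and indices. If any section fails (empty mask or degenerate
#' histogram), the whole call aborts listing the failing indices.
#'
#' @param sections nonempty list of `section_image`s.
#' @param params a [cleaning_params()] object.
#' @return List of cleaned sections.
#' @export
clean_subject <- function(sections, params = cleaning_params()) {
  stopifnot(length(sections) >= 1)
  res <- vector("list", length(sections))
  failed <- integer(0)
  msgs <- character(0)
  for (i in seq_along(sections)) {
    r <- tryCatch(clean_section(sections[[i]], params), error = identity)
    if (inherits(r, "error")) {
      failed <- c(failed, sections[[i]]$index)
      msgs <- c(msgs, conditionMessage(r))
    } else {
      res[[i]] <- r
    }
  }
  if (length(failed)) {
    stop(sprintf("cleaning failed for section index(es) %s: %s",
                 paste(failed, collapse = ", "),
                 paste(unique(msgs), collapse = "; ")))
  }
  res
}
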