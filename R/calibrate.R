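# Gray-level to radioactivity calibration against the co-exposed 14C
# standards. One curve per subject film: standards and film background are
# shared by all sections of a film, so a single calibration applies.

#' Fit a calibration curve to a standards table
#'
#' Natural cubic spline through the `(gray, activity)` standards, mapping
#' 8-bit gray level to radioactivity in nCi/g. Standards must be strictly
#' monotone in both coordinates; at least 4 points are required. A natural
#' spline through monotone knots can still be non-monotone between knots
#' (e.g. on strongly convex data); this is detected on a dense grid and
#' reported as a warning, never silently.
#'
#' @param standards data frame with columns `gray` and `nci_per_g`.
#' @param method `"spline"` (natural cubic, default) or `"linear"`
#'   (piecewise-linear interpolation).
#' @return An object of class `calibration_curve` with fields `knots`,
#'   `fun` (vectorized gray -> activity), `valid_range` and `method`.
#' @export
fit_calibration <- function(standards, method = c("spline", "linear")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(standards),
            all(c("gray", "nci_per_g") %in% names(standards)))
  s <- standards[order(standards$gray), , drop = FALSE]
  if (nrow(s) < 4) stop("too-few-standards: need at least 4 points")
  if (anyDuplicated(s$gray) || any(diff(s$gray) <= 0) ||
      any(diff(s$nci_per_g) <= 0)) {
    stop("invalid-standards: gray and activity must be strictly increasing")
  }
  fun <- if (method == "spline") {
    splinefun(s$gray, s$nci_per_g, method = "natural")
  } else {
    f <- approxfun(s$gray, s$nci_per_g, rule = 2)
    f
  }
  rng <- range(s$gray)
  if (method == "spline") {
    dense <- fun(seq(rng[1], rng[2], length.out = 1024))
    if (any(diff(dense) < -1e-9 * diff(range(dense)))) {
      warning("calibration spline is non-monotone inside its valid range")
    }
  }
  structure(list(knots = s[, c("gray", "nci_per_g")], fun = fun,
                 valid_range = rng, method = method),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> %s, %d standards, gray %g..%g -> %.3g..%.3g nCi/g\n",
    x$method, nrow(x$knots), x$valid_range[1], x$valid_range[2],
    min(x$knots$nci_per_g), max(x$knots$nci_per_g)))
  invisible(x)
}

#' Convert a gray-level section to activities
#'
#' Maps every in-mask pixel through the calibration interpolant. Gray levels
#' outside the fitted range are clamped to the range endpoints by default
#' (film saturation behavior); with `out_of_range = "error"` any such pixel
#' aborts with a count. Masked-out pixels are set to 0 activity.
#'
#' @param section an 8-bit `section_image` (masked or not).
#' @param curve a [fit_calibration()] result.
#' @param out_of_range `"clamp"` or `"error"`.
#' @return Activity-valued `section_image` (nCi/g), same mask.
#' @export
apply_calibration <- function(section, curve,
                              out_of_range = c("clamp", "error")) {
  out_of_range <- match.arg(out_of_range)
  stopifnot(inherits(section, "section_image"),
            inherits(curve, "calibration_curve"))
  px <- section$pixels
  mask <- section$mask
  if (is.null(mask)) mask <- matrix(TRUE, nrow(px), ncol(px))
  g <- px[mask]
  n_out <- sum(g < curve$valid_range[1] | g > curve$valid_range[2])
  if (n_out > 0 && out_of_range == "error") {
    stop(sprintf("out-of-range: %d pixel(s) outside gray range [%g, %g]",
                 n_out, curve$valid_range[1], curve$valid_range[2]))
  }
  g <- pmin(pmax(g, curve$valid_range[1]), curve$valid_range[2])
  act <- matrix(0, nrow(px), ncol(px))
  act[mask] <- curve$fun(g)
  section_image(act, spacing = section$spacing, index = section$index,
                mask = mask)
}
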