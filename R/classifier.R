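# H/S decision region, severity grading, and per-pixel raster classification.
#
# Bleeding is called when the hue/saturation pair of the dyed film falls in a
# calibrated target region near red.  Lightness never enters the decision.
# The generic region form allows a hue wraparound ([0, h_low] U [h_high, 360])
# because hue is circular; the calibrated default is the plain interval
# 3 <= H <= 25, 0.3 <= S <= 0.8.

#' Bleeding decision region in (H, S) space
#'
#' @param h_low,h_high Hue bounds in degrees.  Without wraparound the hue test
#'   is `h_low <= H <= h_high`; with `wraparound = TRUE` the region is the red
#'   wedge `H <= h_low | H >= h_high`.
#' @param s_low,s_high Saturation bounds in `[0, 1]`.
#' @param wraparound Use the circular form `[0, h_low] U [h_high, 360]`.
#' @return An object of class `target_area`.  All four bounds are inclusive.
#' @export
#' @examples
#' target_area()                             # calibrated default
#' target_area(25, 355, wraparound = TRUE)   # generic red wedge
target_area <- function(h_low = 3, h_high = 25, s_low = 0.3, s_high = 0.8,
                        wraparound = FALSE) {
  stopifnot(is.numeric(h_low), is.numeric(h_high),
            is.numeric(s_low), is.numeric(s_high))
  if (!wraparound && !(0 <= h_low && h_low <= h_high && h_high <= 360)) {
    stop("need 0 <= h_low <= h_high <= 360 for a non-wraparound region",
         call. = FALSE)
  }
  if (!(0 <= s_low && s_low <= s_high && s_high <= 1)) {
    stop("need 0 <= s_low <= s_high <= 1", call. = FALSE)
  }
  structure(list(h_low = h_low, h_high = h_high,
                 s_low = s_low, s_high = s_high,
                 wraparound = isTRUE(wraparound)),
            class = "target_area")
}

#' @export
print.target_area <- function(x, ...) {
  hue <- if (x$wraparound) {
    sprintf("H <= %g or H >= %g", x$h_low, x$h_high)
  } else {
    sprintf("%g <= H <= %g", x$h_low, x$h_high)
  }
  cat(sprintf("<target_area> %s, %g <= S <= %g\n", hue, x$s_low, x$s_high))
  invisible(x)
}

#' Severity bands partitioning the bleeding hue range
#'
#' Within the decision region, lower hue means deeper red, i.e. less diluted
#' blood and more severe bleeding.  Two cut-points split the hue range into
#' large / small / trace tiers; the defaults place the 1x and 4x dilution
#' anchors in `large`, 16x and 32x in `small`, and 64x in `trace`.
#'
#' @param cuts Numeric length-2, strictly increasing: hue at or below
#'   `cuts[1]` grades `large`, in `(cuts[1], cuts[2]]` grades `small`, above
#'   `cuts[2]` grades `trace`.
#' @return An object of class `severity_bands`.
#' @export
severity_bands <- function(cuts = c(8, 15)) {
  if (!is.numeric(cuts) || length(cuts) != 2L || anyNA(cuts) ||
      diff(cuts) <= 0) {
    stop("severity configuration error: cuts must be two increasing hues",
         call. = FALSE)
  }
  structure(list(cuts = as.numeric(cuts)), class = "severity_bands")
}

#' Is a colour inside the bleeding decision region?
#'
#' Pure predicate on raw hue/saturation values; all bounds inclusive.
#' Lightness plays no role.  Vectorised.
#'
#' @param h Hue in degrees (vector).
#' @param s Saturation fraction (vector).
#' @param area A [target_area()].
#' @return Logical vector.
#' @export
#' @examples
#' is_bleeding(20, 0.33)   # 64x dilution: TRUE
#' is_bleeding(46, 0.33)   # intestinal juice: FALSE
is_bleeding <- function(h, s, area = target_area()) {
  stopifnot(inherits(area, "target_area"))
  hue_in <- if (area$wraparound) {
    h <= area$h_low | h >= area$h_high
  } else {
    h >= area$h_low & h <= area$h_high
  }
  hue_in & s >= area$s_low & s <= area$s_high
}

.severity_levels <- c("none", "trace", "small", "large")

#' Grade bleeding severity from colour features
#'
#' Non-bleeding colours grade `none`; inside the region the hue band decides
#' the tier (lower hue = more severe).  Vectorised.
#'
#' @inheritParams is_bleeding
#' @param bands A [severity_bands()].
#' @return An ordered factor with levels `none < trace < small < large`.
#' @export
#' @examples
#' grade_severity(c(3, 14, 20, 46), c(0.63, 0.42, 0.33, 0.33))
grade_severity <- function(h, s, area = target_area(),
                           bands = severity_bands()) {
  stopifnot(inherits(bands, "severity_bands"))
  bleeding <- is_bleeding(h, s, area)
  sev <- ifelse(!bleeding, "none",
         ifelse(h <= bands$cuts[1], "large",
         ifelse(h <= bands$cuts[2], "small", "trace")))
  factor(sev, levels = .severity_levels, ordered = TRUE)
}

#' Classify colour features at device reporting precision
#'
#' The capsule's decision path: quantise features to reporting precision
#' (hue to the nearest degree, saturation to two decimals — the precision at
#' which the region thresholds were calibrated) and apply the region test and
#' severity grading.  Vectorised.
#'
#' @inheritParams grade_severity
#' @return A data frame with columns `h`, `s` (reported precision),
#'   `bleeding` (logical) and `severity` (ordered factor).
#' @export
classify_features <- function(h, s, area = target_area(),
                              bands = severity_bands()) {
  rep <- hs_reported(h, s)
  data.frame(
    h = rep$h,
    s = rep$s,
    bleeding = is_bleeding(rep$h, rep$s, area),
    severity = grade_severity(rep$h, rep$s, area, bands)
  )
}

#' Per-pixel bleeding classification of an RGB raster
#'
#' Applies [rgb_to_hsl()] and [is_bleeding()] to every pixel of an RGB image
#' on the 0-255 scale.  Raw (unquantised) features are used per pixel.
#'
#' @param image Either a numeric array `h x w x 3` with values on 0-255, or a
#'   path to a PPM (P3/P6) or PNG file (see [read_image()]).
#' @param area A [target_area()].
#' @return A list with `mask` (integer matrix, 1 = bleeding pixel) and
#'   `fraction` (mean of the mask).
#' @export
#' @examples
#' img <- array(c(255, 128, 0,  0, 128, 0,  0, 128, 255), dim = c(1, 3, 3))
#' classify_image(img, target_area(0, 25, 0.3, 1))
classify_image <- function(image, area = target_area()) {
  if (is.character(image)) image <- read_image(image)
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] < 3L) {
    stop("image format error: need an h x w x 3 array on the 0-255 scale",
         call. = FALSE)
  }
  if (length(image) == 0L) stop("image format error: empty raster",
                                call. = FALSE)
  d <- dim(image)
  hsl <- rgb_to_hsl(as.vector(image[, , 1]), as.vector(image[, , 2]),
                    as.vector(image[, , 3]))
  mask <- matrix(as.integer(is_bleeding(hsl$H, hsl$S, area)),
                 nrow = d[1], ncol = d[2])
  list(mask = mask, fraction = mean(mask))
}
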