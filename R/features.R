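#' Hue bands for green / yellow / brown pixel classes
#'
#' Brown spans 21--50 degrees and yellow 51--80 degrees on the hue circle;
#' the green band is configurable (chlorotic field canopies rarely exceed
#' 140 degrees). Bands are closed on both ends and compared on integer
#' degrees after rounding half-up, which removes boundary ambiguity:
#' hue 50 is brown, hue 51 is yellow.
#'
#' @param brown,yellow,green length-2 numeric `(low, high)` in degrees.
#' @return an object of class `idc_hue_bands`.
#' @export
hue_bands <- function(brown = c(21, 50), yellow = c(51, 80),
                      green = c(81, 140)) {
  bands <- list(brown = brown, yellow = yellow, green = green)
  for (b in bands) {
    stopifnot(is.numeric(b), length(b) == 2L, b[1] <= b[2],
              b[1] >= 0, b[2] < 360)
  }
  # bands must not overlap
  iv <- rbind(brown, yellow, green)
  ord <- order(iv[, 1])
  iv <- iv[ord, , drop = FALSE]
  if (any(iv[-1, 1] <= iv[-nrow(iv), 2])) {
    idc_error("idc_invalid_input", "hue bands must be disjoint")
  }
  structure(bands, class = "idc_hue_bands")
}

# Circular distance from hue h (vector) to the closed band [lo, hi]:
# zero inside, otherwise the smaller circular distance to an endpoint.
band_distance <- function(h, band) {
  inside <- h >= band[1] & h <= band[2]
  d_lo <- abs(circ_diff(h, band[1]))
  d_hi <- abs(circ_diff(h, band[2]))
  ifelse(inside, 0, pmin(d_lo, d_hi))
}

#' Classify canopy pixels as green, yellow or brown
#'
#' Every canopy pixel receives exactly one of the three labels from its
#' hue. Pixels inside a band get that band's label; the few canopy pixels
#' whose hue falls outside all bands (possible after aggressive
#' calibration) are assigned to the nearest band by circular hue distance,
#' with ties resolved in the order brown, yellow, green (the more severe
#' call wins).
#'
#' @param hsv an `idc_hsv` image.
#' @param mask an `idc_mask` from [segment_canopy()] (or a logical matrix).
#' @param bands an `idc_hue_bands` object.
#' @return integer matrix of class `idc_labels`: 0 outside the canopy,
#'   1 = green, 2 = yellow, 3 = brown (see `attr(, "levels")`).
#' @export
classify_canopy_pixels <- function(hsv, mask, bands = hue_bands()) {
  stopifnot(inherits(hsv, "idc_hsv"))
  m <- if (inherits(mask, "idc_mask")) mask$mask else mask
  stopifnot(is.logical(m), all(dim(m) == dim(hsv$h)))
  if (!any(m)) {
    idc_error("idc_no_canopy", "empty canopy mask")
  }
  h <- floor(hsv$h[m] + 0.5) %% 360   # integer degrees, round half-up
  d <- cbind(green = band_distance(h, bands$green),
             yellow = band_distance(h, bands$yellow),
             brown = band_distance(h, bands$brown))
  # ties favor the more severe class: scan brown, then yellow, then green
  lab <- ifelse(d[, "brown"] <= pmin(d[, "yellow"], d[, "green"]), 3L,
         ifelse(d[, "yellow"] <= d[, "green"], 2L, 1L))
  out <- matrix(0L, nrow(m), ncol(m))
  out[m] <- lab
  structure(out, levels = c("green", "yellow", "brown"),
            class = "idc_labels")
}

#' Extract (Y%, B%) canopy discoloration features
#'
#' The two severity features are area fractions of the segmented canopy:
#' `yellow_pct = 100 * n_yellow / n_canopy` (chlorosis) and
#' `brown_pct = 100 * n_brown / n_canopy` (necrosis). The green percentage
#' is the complement, so the three percentages always partition 100.
#'
#' @param labels an `idc_labels` matrix from [classify_canopy_pixels()].
#' @return an object of class `idc_features`: list with `yellow_pct`,
#'   `brown_pct`, `green_pct` and `canopy_pixel_count`.
#' @export
extract_features <- function(labels) {
  stopifnot(inherits(labels, "idc_labels"))
  n <- sum(labels > 0L)
  if (n == 0L) {
    idc_error("idc_no_canopy", "no canopy pixels to extract features from")
  }
  ny <- sum(labels == 2L)
  nb <- sum(labels == 3L)
  y <- 100 * ny / n
  b <- 100 * nb / n
  structure(list(yellow_pct = y, brown_pct = b,
                 green_pct = 100 - y - b,
                 canopy_pixel_count = n),
            class = "idc_features")
}

#' @export
print.idc_features <- function(x, ...) {
  cat(sprintf("canopy features: Y%% = %.2f, B%% = %.2f (%d canopy px)\n",
              x$yellow_pct, x$brown_pct, x$canopy_pixel_count))
  invisible(x)
}

#' Score an image: segmentation through feature extraction
#'
#' Convenience composition of [segment_canopy()],
#' [classify_canopy_pixels()] and [extract_features()].
#'
#' @inheritParams segment_canopy
#' @param bands an `idc_hue_bands` object.
#' @return an `idc_features` object.
#' @export
score_features <- function(image, profile = NULL, config = seg_config(),
                           bands = hue_bands()) {
  if (!is.null(profile)) {
    image <- apply_profile(image, profile)
  }
  hsv <- to_hsv(image)
  mask <- largest_component(threshold_foreground(hsv, config),
                            config$connectivity)
  extract_features(classify_canopy_pixels(hsv, mask, bands))
}
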